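#' @keywords internal
GENO_CODES <- c("QQ", "Qq", "qq")

#' Parse SNP identifiers of the form S<chrom>_<pos>
#'
#' SNP ids follow the GBS convention \code{S<chrom>_<position>}, e.g.
#' \code{S5_10493718} is chromosome 5 at 10493718 bp.
#'
#' @param snp_id character vector of SNP ids.
#' @return data.frame with columns \code{snp}, \code{chrom} (integer),
#'   \code{pos} (double, base pairs).
#' @examples
#' parse_snp_id("S5_10493718")
#' @export
parse_snp_id <- function(snp_id) {
  ok <- grepl("^S[0-9]+_[0-9]+$", snp_id)
  if (!all(ok)) {
    stop("malformed SNP id(s): ", paste(head(snp_id[!ok], 5L), collapse = ", "),
         call. = FALSE)
  }
  body <- sub("^S", "", snp_id)
  parts <- strsplit(body, "_", fixed = TRUE)
  data.frame(
    snp = snp_id,
    chrom = as.integer(vapply(parts, `[`, "", 1L)),
    pos = as.numeric(vapply(parts, `[`, "", 2L)),
    stringsAsFactors = FALSE
  )
}

#' Derive a stage seed from a run-level seed
#'
#' A single run-level seed fans out to per-stage seeds by a fixed documented
#' rule: \code{stage_seed = (seed * 101 + offset) mod (2^31 - 1)}.  Stage
#' offsets are stable across releases so pipelines are reproducible.
#'
#' @param seed integer run-level seed.
#' @param offset integer stage offset (each pipeline stage has a fixed one).
#' @return integer seed suitable for [set.seed()].
#' @export
split_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 101 + offset) %% (2^31 - 1))
}

# internal argument checks -------------------------------------------------

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

.check_fraction <- function(x, name, lo = 0, hi = 1, hi_open = TRUE) {
  bad <- !is.numeric(x) || length(x) != 1L || is.na(x) || x < lo ||
    (if (hi_open) x >= hi else x > hi)
  if (bad) {
    stop(sprintf("`%s` must be in [%g, %g%s", name, lo, hi,
                 if (hi_open) ")" else "]"), call. = FALSE)
  }
  as.numeric(x)
}

.check_codes <- function(codes) {
  bad <- !is.na(codes) & !(codes %in% GENO_CODES)
  if (any(bad)) {
    stop("invalid genotype code(s): ",
         paste(unique(codes[bad])[1:min(5, length(unique(codes[bad])))],
               collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
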