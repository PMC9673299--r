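#' Read a genotype file
#'
#' Two plain-text dialects are supported.  \code{format = "hapmap"} is a
#' HapMap-style TSV with columns \code{rs}, \code{alleles}, \code{chrom},
#' \code{pos} followed by one column per line holding two-letter nucleotide
#' codes (e.g. \code{AA}, \code{AT}, \code{TT}; \code{NN} = missing).  The
#' first allele of the \code{alleles} field is the B73 (reference) allele,
#' so a homozygote for it maps to \code{qq}, a homozygote for the other
#' allele to \code{QQ} (Q = non-B73 allele) and a mixed call to \code{Qq}.
#' \code{format = "matrix"} is a TSV with columns \code{line},
#' \code{family}, then one column per SNP already holding
#' \code{QQ/Qq/qq/NA} codes.
#'
#' @param path file path.
#' @param format \code{"hapmap"} or \code{"matrix"}.
#' @param families optional character vector of family labels for hapmap
#'   input (one per line column); by default families are inferred from
#'   line ids of the form \code{Z<fam>E<line>}, falling back to a single
#'   family.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("hapmap", "matrix"),
                           families = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2L) {
    stop("parse error in ", path, ": need a header and at least one record (line 1)",
         call. = FALSE)
  }
  if (format == "hapmap") .read_hapmap(lines, path, families)
  else .read_matrix(lines, path)
}

.read_hapmap <- function(lines, path, families) {
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("rs", "alleles", "chrom", "pos")
  if (length(header) < 5L || !all(need == header[1:4])) {
    stop("parse error in ", path,
         ": hapmap header must start with rs, alleles, chrom, pos (line 1)",
         call. = FALSE)
  }
  line_ids <- header[-(1:4)]
  n_snps <- length(lines) - 1L
  codes <- matrix(NA_character_, length(line_ids), n_snps)
  snp_ids <- character(n_snps)
  for (i in seq_len(n_snps)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(header)) {
      stop("parse error in ", path, ": wrong field count (line ", i + 1L, ")",
           call. = FALSE)
    }
    snp_ids[i] <- f[1L]
    alleles <- strsplit(f[2L], "/", fixed = TRUE)[[1L]]
    if (length(alleles) != 2L) {
      stop("parse error in ", path, ": bad alleles field '", f[2L],
           "' (line ", i + 1L, ")", call. = FALSE)
    }
    b73 <- alleles[1L]; alt <- alleles[2L]
    gg <- f[-(1:4)]
    known <- c(paste0(b73, b73), paste0(alt, alt), paste0(b73, alt),
               paste0(alt, b73), "NN")
    bad <- !(gg %in% known)
    if (any(bad)) {
      stop("parse error in ", path, ": unknown genotype code '",
           gg[bad][1L], "' (line ", i + 1L, ")", call. = FALSE)
    }
    codes[, i] <- ifelse(gg == "NN", NA_character_,
                  ifelse(gg == paste0(b73, b73), "qq",
                  ifelse(gg == paste0(alt, alt), "QQ", "Qq")))
  }
  dimnames(codes) <- list(line_ids, snp_ids)
  if (is.null(families)) families <- .infer_families(line_ids)
  geno_matrix(codes, families)
}

.read_matrix <- function(lines, path) {
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L || header[1L] != "line" || header[2L] != "family") {
    stop("parse error in ", path,
         ": matrix header must be line, family, <snp ids> (line 1)", call. = FALSE)
  }
  snp_ids <- header[-(1:2)]
  n <- length(lines) - 1L
  codes <- matrix(NA_character_, n, length(snp_ids))
  ids <- character(n); fams <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(header)) {
      stop("parse error in ", path, ": wrong field count (line ", i + 1L, ")",
           call. = FALSE)
    }
    ids[i] <- f[1L]; fams[i] <- f[2L]
    gg <- f[-(1:2)]
    bad <- !(gg %in% c(GENO_CODES, "NA", ""))
    if (any(bad)) {
      stop("parse error in ", path, ": unknown genotype code '", gg[bad][1L],
           "' (line ", i + 1L, ")", call. = FALSE)
    }
    codes[i, ] <- ifelse(gg %in% GENO_CODES, gg, NA_character_)
  }
  dimnames(codes) <- list(ids, snp_ids)
  geno_matrix(codes, fams)
}

.infer_families <- function(line_ids) {
  m <- regmatches(line_ids, regexpr("^Z[0-9]+", line_ids))
  if (length(m) == length(line_ids)) sub("^Z", "F", m) else rep("F01", length(line_ids))
}

#' Write a genotype matrix as HapMap-style TSV
#'
#' The inverse of [read_genotypes()] with \code{format = "hapmap"}: the
#' B73 (q) allele is written as A and the non-B73 (Q) allele as T, so
#' \code{qq -> AA}, \code{Qq -> AT}, \code{QQ -> TT}, missing \code{-> NN}.
#'
#' @param geno a [geno_matrix()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_genotypes_hapmap <- function(geno, path) {
  header <- c("rs", "alleles", "chrom", "pos", geno$lines)
  rows <- vapply(seq_len(ncol(geno$codes)), function(j) {
    g <- geno$codes[, j]
    two <- ifelse(is.na(g), "NN",
           ifelse(g == "qq", "AA", ifelse(g == "Qq", "AT", "TT")))
    paste(c(geno$snps$snp[j], "A/T", geno$snps$chrom[j],
            format(geno$snps$pos[j], scientific = FALSE), two), collapse = "\t")
  }, "")
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  invisible(path)
}

#' Read a long-format phenotype CSV
#'
#' Expects columns \code{line}, \code{family}, \code{env}, \code{trait},
#' \code{value}.  Rows whose value does not parse as a number (e.g.
#' \code{NA}) are dropped and counted in the \code{n_dropped} attribute.
#'
#' @param path CSV file path.
#' @param envs optional integer vector of declared environment ids; any
#'   env label outside this set is a parse error.
#' @return a [pheno_table()] with attribute \code{n_dropped}.
#' @export
read_phenotypes <- function(path, envs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line", "family", "env", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("parse error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  env_int <- suppressWarnings(as.integer(df$env))
  if (anyNA(env_int) || any(env_int < 1L)) {
    stop("parse error in ", path, ": env labels must be positive integers",
         call. = FALSE)
  }
  if (!is.null(envs) && !all(env_int %in% envs)) {
    stop("parse error in ", path, ": env label outside declared set {",
         paste(envs, collapse = ","), "}", call. = FALSE)
  }
  val <- suppressWarnings(as.numeric(df$value))
  keep <- !is.na(val)
  out <- pheno_table(df$line[keep], df$family[keep], env_int[keep],
                     df$trait[keep], val[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Write a phenotype table as CSV
#'
#' @param pheno a [pheno_table()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_phenotypes_csv <- function(pheno, path) {
  utils::write.csv(as.data.frame(pheno)[, c("line", "family", "env", "trait", "value")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
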