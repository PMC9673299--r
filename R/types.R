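#' Construct a genotype matrix object
#'
#' A \code{geno_matrix} stores line-by-SNP genotype codes for a NAM-style
#' population.  Codes follow the Q/q convention with Q the non-B73 allele:
#' \code{QQ} (non-B73 homozygote), \code{Qq} (heterozygote), \code{qq}
#' (B73 homozygote) or \code{NA} (missing call).
#'
#' @param codes character matrix (lines x SNPs) with values in
#'   \code{c("QQ","Qq","qq", NA)}.  Row names are line ids, column names
#'   SNP ids of the form \code{S<chrom>_<pos>}.
#' @param families character vector of family labels, one per line.
#' @return object of class \code{geno_matrix}: a list with elements
#'   \code{codes}, \code{lines}, \code{families} and \code{snps}
#'   (data.frame with \code{snp}, \code{chrom}, \code{pos}).
#' @export
geno_matrix <- function(codes, families) {
  stopifnot(is.matrix(codes), !is.null(rownames(codes)), !is.null(colnames(codes)))
  .check_codes(codes)
  if (length(families) != nrow(codes)) {
    stop("`families` must have one label per line", call. = FALSE)
  }
  snps <- parse_snp_id(colnames(codes))
  structure(
    list(
      codes = codes,
      lines = rownames(codes),
      families = setNames(as.character(families), rownames(codes)),
      snps = snps
    ),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d lines x %d SNPs, %d families\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$families))))
  tab <- table(factor(x$codes, levels = GENO_CODES), useNA = "ifany")
  cat("  code counts:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' Construct a phenotype table
#'
#' Long-format phenotype records: one row per (line, environment, trait)
#' observation.
#'
#' @param line,family character vectors; line id and its family label.
#' @param env integer environment (location) index, 1-based.
#' @param trait character trait name.
#' @param value numeric trait value.
#' @return data.frame of class \code{pheno_table} with those five columns.
#' @export
pheno_table <- function(line, family, env, trait, value) {
  df <- data.frame(
    line = as.character(line), family = as.character(family),
    env = as.integer(env), trait = as.character(trait),
    value = as.numeric(value), stringsAsFactors = FALSE
  )
  if (any(df$env < 1L, na.rm = TRUE)) stop("`env` must be >= 1", call. = FALSE)
  class(df) <- c("pheno_table", "data.frame")
  df
}

#' Construct a genetic architecture
#'
#' The full genetic model writes the phenotype of line k in environment h as
#' \deqn{y_{hk} = \mu + \sum_i a_i x_{A_i} + \sum_i d_i x_{D_i}
#'   + \sum_{i<j} (aa_{ij} x_{AA} + ad_{ij} x_{AD} + da_{ij} x_{DA}
#'   + dd_{ij} x_{DD}) + e_h + \sum_i (ae_{ih} + de_{ih}) u
#'   + \sum_{i<j} (aae + ade + dae + dde)_{ijh} u + \epsilon_{hk}.}
#' A \code{genetic_architecture} stores every coefficient of that model:
#' the mean, per-locus main effects, per-pair digenic epistasis effects,
#' environment effects and per-environment interaction deviations, plus the
#' residual standard deviation.  It is used both as simulation ground truth
#' and as the container for estimated effect sets.
#'
#' @param mu population mean (trait units).
#' @param loci data.frame with columns \code{snp}, \code{a}, \code{d}.
#' @param pairs data.frame with columns \code{snp1}, \code{snp2},
#'   \code{aa}, \code{ad}, \code{da}, \code{dd}; may be empty or NULL.
#' @param env_effects numeric vector of environment effects e_h (one per
#'   environment); \code{NULL} for a single unstructured environment.
#' @param ae,de numeric matrices (loci x environments) of additive-by- and
#'   dominance-by-environment deviations, or NULL for none.
#' @param aae,ade,dae,dde numeric matrices (pairs x environments) of
#'   epistasis-by-environment deviations, or NULL.
#' @param residual_sd residual standard deviation (> 0, trait units).
#' @return object of class \code{genetic_architecture}.
#' @export
genetic_architecture <- function(mu = 0, loci, pairs = NULL,
                                 env_effects = NULL,
                                 ae = NULL, de = NULL,
                                 aae = NULL, ade = NULL, dae = NULL, dde = NULL,
                                 residual_sd = 1) {
  stopifnot(is.data.frame(loci), all(c("snp", "a", "d") %in% names(loci)))
  if (is.null(pairs)) {
    pairs <- data.frame(snp1 = character(), snp2 = character(),
                        aa = numeric(), ad = numeric(), da = numeric(),
                        dd = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("snp1", "snp2", "aa", "ad", "da", "dd") %in% names(pairs)))
  if (nrow(pairs) > 0L) {
    known <- c(pairs$snp1, pairs$snp2) %in% loci$snp
    if (!all(known)) {
      stop("epistatic pairs reference loci absent from `loci`", call. = FALSE)
    }
  }
  # residual_sd = 0 is allowed for noiseless evaluation fixtures
  if (!is.numeric(residual_sd) || residual_sd < 0) {
    stop("`residual_sd` must be >= 0", call. = FALSE)
  }
  n_env <- if (is.null(env_effects)) 1L else length(env_effects)
  chk_mat <- function(m, nr, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (nrow(m) != nr || ncol(m) != n_env) {
      stop(sprintf("`%s` must be %d x %d (terms x environments)", what, nr, n_env),
           call. = FALSE)
    }
    m
  }
  structure(
    list(
      mu = as.numeric(mu),
      loci = loci,
      pairs = pairs,
      env_effects = if (is.null(env_effects)) NULL else as.numeric(env_effects),
      ae = chk_mat(ae, nrow(loci), "ae"),
      de = chk_mat(de, nrow(loci), "de"),
      aae = chk_mat(aae, nrow(pairs), "aae"),
      ade = chk_mat(ade, nrow(pairs), "ade"),
      dae = chk_mat(dae, nrow(pairs), "dae"),
      dde = chk_mat(dde, nrow(pairs), "dde"),
      residual_sd = as.numeric(residual_sd)
    ),
    class = "genetic_architecture"
  )
}

#' @export
print.genetic_architecture <- function(x, ...) {
  cat(sprintf(
    "genetic_architecture: mu=%.3g, %d loci, %d pairs, %s environments, residual_sd=%.3g\n",
    x$mu, nrow(x$loci), nrow(x$pairs),
    if (is.null(x$env_effects)) "1" else length(x$env_effects), x$residual_sd))
  gxe <- c(ae = !is.null(x$ae), de = !is.null(x$de), aae = !is.null(x$aae),
           ade = !is.null(x$ade), dae = !is.null(x$dae), dde = !is.null(x$dde))
  if (any(gxe)) cat("  GxE terms:", paste(names(gxe)[gxe], collapse = ", "), "\n")
  invisible(x)
}

#' @keywords internal
n_envs_of <- function(arch) {
  if (is.null(arch$env_effects)) 1L else length(arch$env_effects)
}
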