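#' @keywords internal
qc_report <- function(n_snps_in, n_snps_out, n_records_in, n_records_out,
                      removed_snps = NULL, removed_records = NULL) {
  if (is.null(removed_snps)) {
    removed_snps <- data.frame(snp = character(), reason = character(),
                               stringsAsFactors = FALSE)
  }
  if (is.null(removed_records)) {
    removed_records <- data.frame(line = character(), env = integer(),
                                  trait = character(), value = numeric(),
                                  reason = character(), stringsAsFactors = FALSE)
  }
  stopifnot(n_snps_in == n_snps_out + nrow(removed_snps),
            n_records_in == n_records_out + nrow(removed_records))
  structure(
    list(n_snps_in = n_snps_in, n_snps_out = n_snps_out,
         n_records_in = n_records_in, n_records_out = n_records_out,
         removed_snps = removed_snps, removed_records = removed_records),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: SNPs %d -> %d, records %d -> %d\n",
              x$n_snps_in, x$n_snps_out, x$n_records_in, x$n_records_out))
  if (nrow(x$removed_snps) > 0L) {
    cat("  removed SNPs by reason:",
        paste(names(table(x$removed_snps$reason)),
              table(x$removed_snps$reason), sep = "=", collapse = ", "), "\n")
  }
  if (nrow(x$removed_records) > 0L) {
    cat("  removed records by reason:",
        paste(names(table(x$removed_records$reason)),
              table(x$removed_records$reason), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Filter SNPs on minor allele frequency and call rate
#'
#' A SNP is discarded when its MAF is strictly below \code{maf_min} or its
#' call rate strictly below \code{call_rate_min}; SNPs sitting exactly on a
#' boundary are kept.  MAF is computed from allele counts with each Qq call
#' contributing one Q and one q; call rate is the fraction of non-missing
#' calls.
#'
#' @param geno a [geno_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param call_rate_min minimum call rate (default 0.90).
#' @return list with elements \code{geno} (filtered [geno_matrix()]) and
#'   \code{report} (a \code{qc_report}).
#' @export
filter_snps <- function(geno, maf_min = 0.05, call_rate_min = 0.90) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (ncol(geno$codes) == 0L) stop("genotype matrix has no SNPs", call. = FALSE)
  codes <- geno$codes
  n_lines <- nrow(codes)
  called <- colSums(!is.na(codes))
  call_rate <- called / n_lines
  nQ <- 2 * colSums(codes == "QQ", na.rm = TRUE) +
    colSums(codes == "Qq", na.rm = TRUE)
  nq <- 2 * colSums(codes == "qq", na.rm = TRUE) +
    colSums(codes == "Qq", na.rm = TRUE)
  total <- nQ + nq
  maf <- ifelse(total > 0, pmin(nQ, nq) / total, 0)

  fail_cr <- call_rate < call_rate_min
  fail_maf <- maf < maf_min
  drop <- fail_cr | fail_maf
  reason <- ifelse(fail_cr, "call_rate", "maf")[drop]

  kept <- geno$codes[, !drop, drop = FALSE]
  out <- geno
  out$codes <- kept
  out$snps <- geno$snps[!drop, , drop = FALSE]
  rownames(out$snps) <- NULL
  report <- qc_report(
    n_snps_in = ncol(codes), n_snps_out = ncol(kept),
    n_records_in = 0L, n_records_out = 0L,
    removed_snps = data.frame(snp = colnames(codes)[drop], reason = reason,
                              stringsAsFactors = FALSE)
  )
  list(geno = out, report = report)
}

#' Remove phenotype outliers by the interquartile-range rule
#'
#' Within each trait-by-environment group, values strictly larger than
#' \code{Q3 + k * IQR} or strictly smaller than \code{Q1 - k * IQR} are
#' removed, where Q1 and Q3 are the first and third quartiles computed by
#' linear interpolation between order statistics ([stats::quantile()] type
#' 7) and IQR = Q3 - Q1.  Groups with fewer than 4 values are skipped with
#' a warning.
#'
#' @param pheno a [pheno_table()].
#' @param k fence multiplier (default 1.5).
#' @return list with elements \code{pheno} (filtered) and \code{report}.
#' @export
remove_phenotype_outliers_iqr <- function(pheno, k = 1.5) {
  grp <- interaction(pheno$trait, pheno$env, drop = TRUE)
  drop <- logical(nrow(pheno))
  for (g in levels(grp)) {
    sel <- which(grp == g)
    if (length(sel) < 4L) {
      warning("IQR outlier removal skipped for group ", g,
              " (fewer than 4 values)", call. = FALSE)
      next
    }
    v <- pheno$value[sel]
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2L] - q[1L]
    out <- v > q[2L] + k * iqr | v < q[1L] - k * iqr
    drop[sel[out]] <- TRUE
  }
  .split_pheno(pheno, drop, "iqr")
}

#' Remove phenotype outliers by standardized residuals
#'
#' Fits the baseline model (trait-by-environment group means), standardizes
#' the residuals within each group and removes records with
#' \code{|resid - mean(resid)| / sd(resid) > k}.  Groups whose residual
#' standard deviation is zero are left untouched with a warning.
#'
#' @param pheno a [pheno_table()].
#' @param k standardized-residual cutoff (default 3).
#' @return list with elements \code{pheno} (filtered) and \code{report}.
#' @export
remove_residual_outliers <- function(pheno, k = 3) {
  grp <- interaction(pheno$trait, pheno$env, drop = TRUE)
  drop <- logical(nrow(pheno))
  for (g in levels(grp)) {
    sel <- which(grp == g)
    res <- pheno$value[sel] - mean(pheno$value[sel])
    s <- sd(res)
    if (!is.finite(s) || s == 0) {
      warning("residual outlier removal skipped for group ", g,
              " (zero residual variance)", call. = FALSE)
      next
    }
    drop[sel[abs(res - mean(res)) / s > k]] <- TRUE
  }
  .split_pheno(pheno, drop, "residual")
}

.split_pheno <- function(pheno, drop, reason) {
  removed <- data.frame(
    line = pheno$line[drop], env = pheno$env[drop], trait = pheno$trait[drop],
    value = pheno$value[drop], reason = if (any(drop)) reason else character(0),
    stringsAsFactors = FALSE
  )
  kept <- pheno[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("pheno_table", "data.frame")
  report <- qc_report(
    n_snps_in = 0L, n_snps_out = 0L,
    n_records_in = nrow(pheno), n_records_out = nrow(kept),
    removed_records = removed
  )
  list(pheno = kept, report = report)
}

#' Write a QC report as TSV
#'
#' @param report a \code{qc_report}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_qc_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# SNPs\t%d -> %d", report$n_snps_in, report$n_snps_out), con)
  writeLines(sprintf("# records\t%d -> %d", report$n_records_in,
                     report$n_records_out), con)
  if (nrow(report$removed_snps) > 0L) {
    write.table(cbind(what = "snp", report$removed_snps), con, sep = "\t",
                row.names = FALSE, col.names = TRUE, quote = FALSE)
  }
  if (nrow(report$removed_records) > 0L) {
    write.table(cbind(what = "record", report$removed_records), con, sep = "\t",
                row.names = FALSE, col.names = TRUE, quote = FALSE)
  }
  invisible(path)
}
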