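#' Score statistic for GMDR scanning
#'
#' Residuals of the phenotype from a mean-plus-environment model (the
#' grand mean of each trait-by-environment group), the quantitative-trait
#' generalization of the GMDR score statistic.
#'
#' @param pheno a [pheno_table()] holding a single trait.
#' @return data.frame with columns \code{line}, \code{env}, \code{resid},
#'   one row per phenotype record.
#' @export
gmdr_residuals <- function(pheno) {
  if (length(unique(pheno$trait)) > 1L) {
    stop("`pheno` must hold a single trait", call. = FALSE)
  }
  grp <- interaction(pheno$trait, pheno$env, drop = TRUE)
  mu <- tapply(pheno$value, grp, mean)
  data.frame(line = pheno$line, env = pheno$env,
             resid = pheno$value - mu[grp], stringsAsFactors = FALSE)
}

#' GMDR score of a locus tuple
#'
#' Generalized multifactor dimensionality reduction: records are binned
#' into cells by their genotype combination at the tuple's loci (1 to 3
#' loci, 3 to 27 cells).  Within each cross-validation training split, a
#' cell is labeled high-risk when its mean score statistic (phenotype
#' residual) exceeds the overall training mean; held-out records are then
#' classified by their cell's label and the score is the cross-validated
#' balanced accuracy of that classification against the records' own
#' high/low status.  Cells with no training members contribute no test
#' counts.  A locus tuple unrelated to the phenotype scores near 0.5; a
#' fully determining tuple scores 1.
#'
#' @param residuals output of [gmdr_residuals()] (or any data.frame with
#'   \code{line} and \code{resid}).
#' @param geno a [geno_matrix()].
#' @param loci character vector of 1-3 SNP ids.
#' @param n_folds number of cross-validation folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return balanced-accuracy score in [0, 1].
#' @export
gmdr_score <- function(residuals, geno, loci, n_folds = 5, seed = 1L) {
  if (!length(loci) %in% 1:3) stop("tuple size must be 1, 2 or 3", call. = FALSE)
  codes <- geno$codes[match(residuals$line, geno$lines), loci, drop = FALSE]
  cell <- apply(codes, 1L, paste, collapse = "/")
  ok <- !apply(codes, 1L, anyNA)
  cell <- cell[ok]
  res <- residuals$resid[ok]
  n <- length(res)
  if (n < n_folds) stop("too few records for the requested folds", call. = FALSE)
  fold <- withr::with_seed(seed, sample(rep_len(seq_len(n_folds), n)))

  accs <- numeric(0)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    m <- mean(res[tr])
    cm <- tapply(res[tr], cell[tr], mean)
    te <- which(!tr & cell %in% names(cm))
    if (length(te) == 0L) next
    pred_high <- cm[cell[te]] > m
    true_high <- res[te] > m
    sens <- if (any(true_high)) mean(pred_high[true_high]) else NA_real_
    spec <- if (any(!true_high)) mean(!pred_high[!true_high]) else NA_real_
    accs <- c(accs, mean(c(sens, spec), na.rm = TRUE))
  }
  if (length(accs) == 0L) return(NA_real_)
  mean(accs)
}

#' GMDR-style prescreening scan
#'
#' Scans SNPs for main effects (1D) and locus tuples for epistasis (2D,
#' 3D) using the GMDR balanced-accuracy score, and returns the top-ranked
#' candidates per dimension.  The 1D scan is exhaustive; 2D and 3D scans
#' are restricted to tuples formed from the \code{survivors} top 1D SNPs
#' for tractability.  Ranking ties are broken by (chromosome, position)
#' order so results are deterministic.
#'
#' @param pheno a [pheno_table()] holding one trait.
#' @param geno a [geno_matrix()].
#' @param dims integer subset of \code{c(1, 2, 3)}.
#' @param top_k number of candidates kept per dimension.
#' @param n_folds cross-validation folds passed to [gmdr_score()].
#' @param survivors number of top 1D SNPs eligible for 2D/3D tuples.
#' @param seed integer seed.
#' @return object of class \code{candidate_set}: list with data.frames
#'   \code{loci} (snp, score), \code{pairs} (snp1, snp2, score),
#'   \code{triples}, and \code{params}.  Tuples are expanded into their
#'   constituent loci and pairs for the association stage via
#'   [candidate_terms()].
#' @export
gmdr_scan <- function(pheno, geno, dims = c(1L, 2L), top_k = 20L,
                      n_folds = 5L, survivors = 30L, seed = 1L) {
  if (!all(dims %in% 1:3)) stop("`dims` must be a subset of {1, 2, 3}", call. = FALSE)
  top_k <- .check_count(top_k, "top_k")
  res <- gmdr_residuals(pheno)
  snps <- geno$snps

  order_tiebreak <- function(score, chrom, pos) {
    order(-score, chrom, pos)
  }

  scores_1d <- vapply(snps$snp, function(s)
    gmdr_score(res, geno, s, n_folds = n_folds, seed = seed), 0)
  o <- order_tiebreak(scores_1d, snps$chrom, snps$pos)
  loci_df <- data.frame(snp = snps$snp[o], score = scores_1d[o],
                        stringsAsFactors = FALSE)
  surv <- head(loci_df$snp, survivors)

  pairs_df <- data.frame(snp1 = character(), snp2 = character(),
                         score = numeric(), stringsAsFactors = FALSE)
  if (2L %in% dims && length(surv) >= 2L) {
    cmb <- utils::combn(surv, 2L)
    sc <- vapply(seq_len(ncol(cmb)), function(j)
      gmdr_score(res, geno, cmb[, j], n_folds = n_folds, seed = seed), 0)
    key <- .tuple_key(cmb, snps)
    o <- order(-sc, key)
    pairs_df <- data.frame(snp1 = cmb[1L, o], snp2 = cmb[2L, o], score = sc[o],
                           stringsAsFactors = FALSE)
    pairs_df <- head(pairs_df, top_k)
  }

  triples_df <- data.frame(snp1 = character(), snp2 = character(),
                           snp3 = character(), score = numeric(),
                           stringsAsFactors = FALSE)
  if (3L %in% dims && length(surv) >= 3L) {
    cmb <- utils::combn(surv, 3L)
    sc <- vapply(seq_len(ncol(cmb)), function(j)
      gmdr_score(res, geno, cmb[, j], n_folds = n_folds, seed = seed), 0)
    key <- .tuple_key(cmb, snps)
    o <- order(-sc, key)
    triples_df <- data.frame(snp1 = cmb[1L, o], snp2 = cmb[2L, o],
                             snp3 = cmb[3L, o], score = sc[o],
                             stringsAsFactors = FALSE)
    triples_df <- head(triples_df, top_k)
  }

  structure(
    list(loci = head(loci_df, top_k),
         pairs = pairs_df,
         triples = triples_df,
         params = list(dims = dims, top_k = top_k, n_folds = n_folds,
                       survivors = survivors, seed = seed)),
    class = "candidate_set"
  )
}

# deterministic tuple ordering key: genome order of member loci
.tuple_key <- function(cmb, snps) {
  idx <- matrix(match(cmb, snps$snp), nrow = nrow(cmb))
  apply(idx, 2L, function(ii)
    paste(sprintf("%03d_%012.0f", snps$chrom[ii], snps$pos[ii]), collapse = "|"))
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d loci, %d pairs, %d triples (dims = %s)\n",
              nrow(x$loci), nrow(x$pairs), nrow(x$triples),
              paste(x$params$dims, collapse = ",")))
  invisible(x)
}

#' Expand a candidate set into association-model terms
#'
#' Collects the loci to model (union of 1D hits and tuple members) and the
#' pairs to model (2D hits plus all pairs within each 3D triple), ready for
#' [build_design()].
#'
#' @param cs a \code{candidate_set} from [gmdr_scan()].
#' @return list with \code{loci} (character) and \code{pairs} (data.frame
#'   snp1, snp2).
#' @export
candidate_terms <- function(cs) {
  loci <- unique(c(cs$loci$snp, cs$pairs$snp1, cs$pairs$snp2,
                   cs$triples$snp1, cs$triples$snp2, cs$triples$snp3))
  pairs <- cs$pairs[, c("snp1", "snp2"), drop = FALSE]
  if (nrow(cs$triples) > 0L) {
    for (i in seq_len(nrow(cs$triples))) {
      tri <- unlist(cs$triples[i, c("snp1", "snp2", "snp3")], use.names = FALSE)
      cmb <- utils::combn(tri, 2L)
      pairs <- rbind(pairs, data.frame(snp1 = cmb[1L, ], snp2 = cmb[2L, ],
                                       stringsAsFactors = FALSE))
    }
  }
  pairs <- unique(pairs)
  rownames(pairs) <- NULL
  list(loci = loci, pairs = pairs)
}

#' Write a candidate set as TSV
#'
#' @param cs a \code{candidate_set}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_candidate_set <- function(cs, path) {
  rows <- character(0)
  if (nrow(cs$loci) > 0L) {
    rows <- c(rows, sprintf("1D\t%d\t%s\t%.6f", seq_len(nrow(cs$loci)),
                            cs$loci$snp, cs$loci$score))
  }
  if (nrow(cs$pairs) > 0L) {
    rows <- c(rows, sprintf("2D\t%d\t%s,%s\t%.6f", seq_len(nrow(cs$pairs)),
                            cs$pairs$snp1, cs$pairs$snp2, cs$pairs$score))
  }
  if (nrow(cs$triples) > 0L) {
    rows <- c(rows, sprintf("3D\t%d\t%s,%s,%s\t%.6f", seq_len(nrow(cs$triples)),
                            cs$triples$snp1, cs$triples$snp2, cs$triples$snp3,
                            cs$triples$score))
  }
  writeLines(c("dim\trank\ttuple\tscore", rows), path)
  invisible(path)
}
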