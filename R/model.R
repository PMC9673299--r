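#' Fit the full genetic mixed model
#'
#' Fits the full genetic model to the phenotype records of a design:
#' genetic main effects and digenic epistasis are fixed; the environment
#' effect and every gene-by-environment interaction family (AE, DE, AAE,
#' ADE, DAE, DDE) are random with one variance component per family.
#' Variance components are estimated by restricted maximum likelihood
#' (REML), profiled over the residual variance and optimized on the log
#' variance-ratio scale; the Woodbury identity keeps every evaluation at
#' the cost of the (small) number of random columns rather than the number
#' of records.  Collinear fixed columns are pruned (recorded in
#' \code{$pruned}) before fitting.
#'
#' @param dm a [build_design()] result.
#' @param y numeric response; defaults to the design's phenotype values.
#' @return object of class \code{fgm_fit}: fixed estimates \code{beta} and
#'   standard errors \code{se}, variance components \code{vc} (per random
#'   block, plus \code{residual}), realized random effects (BLUPs)
#'   \code{blup}, the pruned column names, the design, and REML details.
#' @export
fit_full_model <- function(dm, y = dm$records$value) {
  stopifnot(inherits(dm, "design_matrices"))
  if (length(y) != nrow(dm$X)) {
    stop("response length does not match the design rows", call. = FALSE)
  }
  n <- length(y)
  Xf <- cbind(`(Intercept)` = 1, dm$C, dm$X)

  # prune collinear fixed columns
  qr_f <- qr(Xf)
  keep <- qr_f$pivot[seq_len(qr_f$rank)]
  pruned <- colnames(Xf)[setdiff(seq_len(ncol(Xf)), keep)]
  X <- Xf[, sort(keep), drop = FALSE]
  p <- ncol(X)

  # random blocks: drop blocks with no non-zero column
  Zb <- dm$Z[vapply(dm$Z, function(z) any(z != 0), TRUE)]
  dropped_blocks <- setdiff(names(dm$Z), names(Zb))
  B <- length(Zb)

  if (B == 0L) {
    fit <- lm.fit(X, y)
    s2 <- sum(fit$residuals^2) / (n - p)
    XtXinv <- chol2inv(chol(crossprod(X)))
    out <- structure(
      list(beta = setNames(fit$coefficients, colnames(X)),
           se = setNames(sqrt(diag(XtXinv) * s2), colnames(X)),
           vc = data.frame(block = "residual", sigma2 = s2),
           blup = list(), pruned = pruned, dropped_blocks = dropped_blocks,
           design = dm, y = y, n = n, p = p,
           reml = list(converged = TRUE, logLik = NA_real_)),
      class = "fgm_fit")
    return(out)
  }

  Z <- do.call(cbind, Zb)
  qb <- vapply(Zb, ncol, 0L)
  block_of <- rep(seq_len(B), qb)
  q <- ncol(Z)

  XtX <- crossprod(X); Xty <- crossprod(X, y)
  ZtZ <- crossprod(Z); ZtX <- crossprod(Z, X); Zty <- crossprod(Z, y)
  yty <- sum(y * y)

  eval_reml <- function(log_gamma) {
    g <- exp(log_gamma)[block_of]
    sg <- sqrt(g)
    M <- ZtZ * tcrossprod(sg)
    diag(M) <- diag(M) + 1
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) return(list(obj = 1e10))
    SZtX <- ZtX * sg; SZty <- Zty * sg
    MiZtX <- backsolve(R, forwardsolve(t(R), SZtX))
    MiZty <- backsolve(R, forwardsolve(t(R), SZty))
    XtVX <- XtX - crossprod(SZtX, MiZtX)
    XtVy <- Xty - crossprod(SZtX, MiZty)
    ytVy <- yty - crossprod(SZty, MiZty)
    Rx <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(Rx)) return(list(obj = 1e10))
    beta <- backsolve(Rx, forwardsolve(t(Rx), XtVy))
    rss <- drop(ytVy - crossprod(XtVy, beta))
    if (rss <= 0) rss <- .Machine$double.eps
    s2 <- rss / (n - p)
    obj <- (n - p) * log(s2) + 2 * sum(log(diag(R))) + 2 * sum(log(diag(Rx)))
    list(obj = drop(obj), beta = drop(beta), s2 = s2, R = R, Rx = Rx, sg = sg)
  }

  opt <- optim(rep(log(0.1), B), function(lg) eval_reml(lg)$obj,
               method = if (B == 1L) "Brent" else "Nelder-Mead",
               lower = if (B == 1L) -25 else -Inf,
               upper = if (B == 1L) 25 else Inf,
               control = list(maxit = 2000, reltol = 1e-10))
  sol <- eval_reml(opt$par)
  gamma <- exp(opt$par)
  s2 <- sol$s2
  beta <- setNames(sol$beta, colnames(X))

  # BLUPs: u = Gamma Z' V0^{-1} r with r = y - X beta
  Ztr <- drop(Zty - ZtX %*% sol$beta)
  sg <- sol$sg
  # Z'V0^{-1} r = Z'r - Z'Z S^{1/2} M^{-1} S^{1/2} Z'r
  tmp <- backsolve(sol$R, forwardsolve(t(sol$R), sg * Ztr))
  u <- gamma[block_of] * drop(Ztr - ZtZ %*% (sg * tmp))
  names(u) <- colnames(Z)
  blup <- split(u, block_of)
  names(blup) <- names(Zb)

  XtVXinv <- chol2inv(sol$Rx)
  vc <- data.frame(
    block = c(names(Zb), "residual"),
    sigma2 = c(gamma * s2, s2),
    stringsAsFactors = FALSE
  )
  structure(
    list(beta = beta, se = setNames(sqrt(pmax(diag(XtVXinv), 0) * s2), colnames(X)),
         vc = vc, blup = blup, pruned = pruned, dropped_blocks = dropped_blocks,
         design = dm, y = y, n = n, p = p,
         reml = list(converged = opt$convergence == 0, gamma = gamma,
                     logLik = -0.5 * sol$obj)),
    class = "fgm_fit")
}

#' @export
print.fgm_fit <- function(x, ...) {
  cat(sprintf("fgm_fit: %d records, %d fixed effects (%d pruned)\n",
              x$n, x$p, length(x$pruned)))
  cat("variance components:\n")
  print(x$vc, row.names = FALSE)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Henderson method III F tests

#' Henderson method III F-test of a model term
#'
#' Tests a term of the full genetic model by the method III device:
#' differences of reductions in sums of squares between the complete model
#' and the model with the term's columns dropped, scaled by the complete
#' model's residual mean square.  Random terms (blocks) are tested by the
#' same quadratic form, which compares the block's contribution against
#' its expectation under the null of a zero variance component.  On a
#' balanced fixed-only design this F coincides with the classical ANOVA F.
#'
#' @param fitted an \code{fgm_fit} (or a \code{design_matrices} plus
#'   \code{y}).
#' @param term one or more fixed-effect column names (e.g.
#'   \code{"a@S1_100000"}, or both main-effect columns of a locus for a
#'   joint 2-df test) or a single random block name (e.g. \code{"AE"},
#'   \code{"env"}).
#' @param y response when \code{fitted} is a design.
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p} (pointwise).
#' @export
henderson_f <- function(fitted, term, y = NULL) {
  if (inherits(fitted, "fgm_fit")) {
    dm <- fitted$design; y <- fitted$y
  } else if (inherits(fitted, "design_matrices")) {
    dm <- fitted
    if (is.null(y)) y <- dm$records$value
  } else stop("`fitted` must be an fgm_fit or design_matrices", call. = FALSE)

  W_parts <- c(list(`(Intercept)` = matrix(1, nrow(dm$X), 1,
                                           dimnames = list(NULL, "(Intercept)")),
                    C = dm$C, X = dm$X), dm$Z)
  W <- do.call(cbind, W_parts)
  part_of <- rep(names(W_parts), vapply(W_parts, ncol, 0L))

  if (all(term %in% colnames(dm$X))) {
    # fixed terms are spanned by their own environment-masked interaction
    # columns; exclude those from both reductions so the contrast is
    # estimable (the interaction blocks are tested separately)
    gxe_prefix <- c(a = "ae", d = "de", aa = "aae", ad = "ade",
                    da = "dae", dd = "dde")
    own <- paste0("^", gxe_prefix[sub("@.*$", "", term)], "@",
                  sub("^[a-z]+@", "", term), ":env")
    excl <- which(Reduce(`|`, lapply(own, grepl, x = colnames(W))))
    if (length(excl) > 0L) {
      W <- W[, -excl, drop = FALSE]
      part_of <- part_of[-excl]
    }
    drop_cols <- which(part_of == "X")[colnames(dm$X) %in% term]
  } else if (length(term) == 1L && term %in% names(dm$Z)) {
    drop_cols <- which(part_of == term)
  } else {
    stop("term not present in model: ", paste(term, collapse = ", "),
         call. = FALSE)
  }

  qr_full <- qr(W)
  r_full <- qr_full$rank
  df2 <- length(y) - r_full
  if (df2 <= 0) stop("no residual degrees of freedom for the F test", call. = FALSE)
  ssr_full <- sum(qr.fitted(qr_full, y)^2)
  mse <- (sum(y^2) - ssr_full) / df2

  qr_red <- qr(W[, -drop_cols, drop = FALSE])
  df1 <- r_full - qr_red$rank
  if (df1 == 0L) {
    return(list(F = 0, df1 = 0L, df2 = df2, p = 1))
  }
  ssr_red <- sum(qr.fitted(qr_red, y)^2)
  Fv <- ((ssr_full - ssr_red) / df1) / mse
  list(F = Fv, df1 = df1, df2 = df2,
       p = pf(Fv, df1, df2, lower.tail = FALSE))
}

# ---------------------------------------------------------------------------
# Marginal Henderson-III association scan

# orthonormal basis of the baseline model space (intercept + env + PCs)
.base_Q <- function(pheno, pcs = NULL) {
  env <- factor(pheno$env)
  M <- if (nlevels(env) > 1L) model.matrix(~env) else
    matrix(1, nrow(pheno), 1L)
  if (!is.null(pcs) && ncol(pcs) > 0L) M <- cbind(M, pcs)
  qr_b <- qr(M)
  list(Q = qr.Q(qr_b)[, seq_len(qr_b$rank), drop = FALSE], rank = qr_b$rank)
}

.residualize <- function(M, Q) M - Q %*% crossprod(Q, M)

# vectorized per-locus F tests for a and d terms given residualized
# coefficient matrices; returns list of vectors
.main_scan_F <- function(yr, Ar, Dr, rank_base, tol = 1e-10) {
  n <- length(yr)
  Saa <- colSums(Ar^2); Sdd <- colSums(Dr^2); Sad <- colSums(Ar * Dr)
  Say <- drop(crossprod(Ar, yr)); Sdy <- drop(crossprod(Dr, yr))
  Syy <- sum(yr^2)
  scale <- pmax(Saa, 1) * pmax(Sdd, 1)
  det <- Saa * Sdd - Sad^2
  a_ok <- Saa > tol
  d_ok <- Sdd > tol & det > tol * scale     # d column informative and not aliased
  df_model <- as.integer(a_ok) + as.integer(d_ok)

  ssr_a <- ifelse(a_ok, Say^2 / pmax(Saa, tol), 0)
  ssr_d <- ifelse(Sdd > tol, Sdy^2 / pmax(Sdd, tol), 0)
  ssr_full <- ifelse(d_ok & a_ok,
                     (Sdd * Say^2 - 2 * Sad * Say * Sdy + Saa * Sdy^2) /
                       ifelse(det > 0, det, 1),
                     ifelse(a_ok, ssr_a, ifelse(Sdd > tol, ssr_d, 0)))
  df2 <- n - rank_base - df_model
  mse <- (Syy - ssr_full) / pmax(df2, 1)
  mse <- pmax(mse, .Machine$double.eps)
  F_a <- ifelse(a_ok, (ssr_full - ifelse(d_ok, ssr_d, 0)) / mse, 0)
  F_d <- ifelse(d_ok, (ssr_full - ssr_a) / mse, 0)
  list(F_a = pmax(F_a, 0), F_d = pmax(F_d, 0), df2 = df2,
       a_ok = a_ok, d_ok = d_ok)
}

#' Marginal Henderson-III association scan
#'
#' Scans candidate loci (and optionally locus pairs) one term at a time:
#' each locus is tested in the model \code{y ~ environment (+ PCs) +
#' additive + dominance}, with a Henderson-III reduction F for each of the
#' additive and dominance terms; each pair is tested in a model that adds
#' both loci's main effects and the four digenic epistasis contrasts, with
#' an F per epistasis term.  Terms belong to families (\code{main},
#' \code{epistasis}) used by [permutation_threshold()] for family-wise
#' max-F thresholds.
#'
#' @param geno a [geno_matrix()].
#' @param pheno a [pheno_table()] with one trait.
#' @param loci character vector of candidate SNP ids.
#' @param pairs data.frame with columns snp1, snp2, or NULL.
#' @param n_pcs number of principal-component cofactors (0 = base model).
#' @return data.frame with columns \code{term}, \code{type}, \code{family},
#'   \code{F}, \code{df1}, \code{df2}, \code{p} and \code{neg_log10_p}.
#' @export
henderson_scan <- function(geno, pheno, loci, pairs = NULL, n_pcs = 0) {
  sc <- .scan_context(geno, pheno, loci, pairs, n_pcs)
  .scan_F_table(sc, sc$yr)
}

# precompute everything reusable across permutations
.scan_context <- function(geno, pheno, loci, pairs = NULL, n_pcs = 0) {
  pcs <- if (n_pcs > 0) {
    compute_pcs(geno, n_pcs)[match(pheno$line, geno$lines), , drop = FALSE]
  } else NULL
  base <- .base_Q(pheno, pcs)
  all_loci <- union(loci, c(pairs$snp1, pairs$snp2))
  coefs <- locus_coefficients(geno, all_loci)
  idx <- match(pheno$line, rownames(coefs$xA))
  A <- coefs$xA[idx, loci, drop = FALSE]
  D <- coefs$xD[idx, loci, drop = FALSE]
  Ar <- .residualize(A, base$Q)
  Dr <- .residualize(D, base$Q)
  y <- pheno$value
  yr <- drop(y - base$Q %*% crossprod(base$Q, y))

  pair_ctx <- NULL
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    pcf <- pair_coefficients(coefs, pairs)
    pair_ctx <- lapply(seq_len(nrow(pairs)), function(p) {
      M <- cbind(
        coefs$xA[idx, pairs$snp1[p]], coefs$xD[idx, pairs$snp1[p]],
        coefs$xA[idx, pairs$snp2[p]], coefs$xD[idx, pairs$snp2[p]],
        aa = pcf$xAA[idx, p], ad = pcf$xAD[idx, p],
        da = pcf$xDA[idx, p], dd = pcf$xDD[idx, p])
      Mr <- .residualize(M, base$Q)
      qf <- qr(Mr)
      Qf <- qr.Q(qf)[, seq_len(qf$rank), drop = FALSE]
      reds <- lapply(5:8, function(j) {
        qr_r <- qr(Mr[, -j, drop = FALSE])
        list(Q = qr.Q(qr_r)[, seq_len(qr_r$rank), drop = FALSE], rank = qr_r$rank)
      })
      list(Qf = Qf, rank_full = qf$rank, reds = reds,
           name = paste(pairs$snp1[p], pairs$snp2[p], sep = "x"))
    })
  }
  list(yr = yr, Ar = Ar, Dr = Dr, base = base, loci = loci,
       pairs = pairs, pair_ctx = pair_ctx, env = pheno$env, y = y, Q = base$Q,
       n = length(y))
}

# scan table for one (possibly permuted) residualized response
.scan_F_table <- function(sc, yr) {
  ms <- .main_scan_F(yr, sc$Ar, sc$Dr, sc$base$rank)
  tab <- data.frame(
    term = c(paste0("a@", sc$loci), paste0("d@", sc$loci)),
    type = rep(c("a", "d"), each = length(sc$loci)),
    family = "main",
    F = c(ms$F_a, ms$F_d),
    df1 = c(as.integer(ms$a_ok), as.integer(ms$d_ok)),
    df2 = rep(ms$df2, 2L),
    stringsAsFactors = FALSE
  )
  if (!is.null(sc$pair_ctx)) {
    types <- c("aa", "ad", "da", "dd")
    rows <- lapply(sc$pair_ctx, function(pcx) {
      ssr_full <- sum(crossprod(pcx$Qf, yr)^2)
      df2 <- sc$n - sc$base$rank - pcx$rank_full
      mse <- max((sum(yr^2) - ssr_full) / max(df2, 1), .Machine$double.eps)
      Fv <- numeric(4L); df1 <- integer(4L)
      for (j in 1:4) {
        red <- pcx$reds[[j]]
        d1 <- pcx$rank_full - red$rank
        df1[j] <- d1
        Fv[j] <- if (d1 == 0L) 0 else
          max((ssr_full - sum(crossprod(red$Q, yr)^2)) / d1 / mse, 0)
      }
      data.frame(term = paste0(types, "@", pcx$name), type = types,
                 family = "epistasis", F = Fv, df1 = df1, df2 = df2,
                 stringsAsFactors = FALSE)
    })
    tab <- rbind(tab, do.call(rbind, rows))
  }
  tab$p <- ifelse(tab$df1 > 0,
                  pf(tab$F, pmax(tab$df1, 1), pmax(tab$df2, 1),
                     lower.tail = FALSE), 1)
  tab$neg_log10_p <- -log10(pmax(tab$p, .Machine$double.xmin))
  tab
}
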