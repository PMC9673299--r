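#' Permutation experiment-wise significance thresholds
#'
#' Estimates critical F-values controlling the experiment-wise type I
#' error of the marginal association scan.  Phenotype records are permuted
#' within environment (preserving the environment structure while
#' breaking the genotype-phenotype link); for each permutation the scan is
#' recomputed and the maximum F is recorded separately per term family
#' (\code{main}, \code{epistasis}).  The critical F of a family is the
#' \code{(1 - alpha)} empirical quantile (type 1, so \code{alpha = 1}
#' returns the minimum permuted max-F) of its max-F distribution, and each
#' observed term receives an experiment-wise P-value
#' \code{P_EW = (1 + #\{max-F >= F_obs\}) / (1 + n_perm)}.  Significance
#' uses the exact rule \code{P_EW <= alpha}, which controls the
#' family-wise error at \code{alpha} even with a finite number of
#' permutations.
#'
#' @param geno a [geno_matrix()].
#' @param pheno a [pheno_table()] with one trait.
#' @param loci candidate SNP ids.
#' @param pairs data.frame snp1/snp2 of candidate pairs, or NULL.
#' @param n_perm number of permutations (default 2000; fewer than 100 is
#'   refused unless \code{force = TRUE}).
#' @param alpha experiment-wise type I error level (default 0.05).
#' @param seed integer seed for the permutation draws.
#' @param n_pcs number of principal-component cofactors.
#' @param exhaustive if TRUE, enumerate every within-environment
#'   permutation instead of sampling (only feasible for tiny data; guarded
#'   at 100000 permutations).
#' @param force allow \code{n_perm < 100}.
#' @return list with \code{terms} (the observed scan plus \code{p_ew} and
#'   \code{significant}), \code{critical} (named critical F per family),
#'   \code{max_f} (permutation max-F matrix), \code{n_perm}, \code{alpha}.
#' @export
permutation_threshold <- function(geno, pheno, loci, pairs = NULL,
                                  n_perm = 2000L, alpha = 0.05, seed = 1L,
                                  n_pcs = 0, exhaustive = FALSE,
                                  force = FALSE) {
  alpha <- .check_fraction(alpha, "alpha", lo = 0, hi = 1, hi_open = FALSE)
  if (!exhaustive) {
    n_perm <- .check_count(n_perm, "n_perm")
    if (n_perm < 100L && !force) {
      stop("`n_perm` < 100 gives unreliable thresholds; use force = TRUE to override",
           call. = FALSE)
    }
    if (n_perm < 100L) warning("n_perm < 100: thresholds are unreliable",
                               call. = FALSE)
  }

  sc <- .scan_context(geno, pheno, loci, pairs, n_pcs)
  obs <- .scan_F_table(sc, sc$yr)
  fams <- unique(obs$family)

  env_groups <- split(seq_along(sc$y), sc$env)
  perms <- if (exhaustive) {
    .enumerate_within_env(env_groups, limit = 100000L)
  } else {
    withr::with_seed(seed, lapply(seq_len(n_perm), function(i) {
      idx <- seq_along(sc$y)
      for (g in env_groups) idx[g] <- g[sample.int(length(g))]
      idx
    }))
  }
  n_perm_eff <- length(perms)

  max_f <- matrix(NA_real_, n_perm_eff, length(fams),
                  dimnames = list(NULL, fams))
  for (i in seq_len(n_perm_eff)) {
    yp <- sc$y[perms[[i]]]
    ypr <- drop(yp - sc$Q %*% crossprod(sc$Q, yp))
    tab <- .scan_F_table(sc, ypr)
    for (fam in fams) max_f[i, fam] <- max(tab$F[tab$family == fam])
  }

  critical <- vapply(fams, function(fam)
    quantile(max_f[, fam], probs = 1 - alpha, type = 1, names = FALSE), 0)
  obs$p_ew <- vapply(seq_len(nrow(obs)), function(i) {
    fam <- obs$family[i]
    (1 + sum(max_f[, fam] >= obs$F[i])) / (1 + n_perm_eff)
  }, 0)
  # exact permutation rule: the observed statistic joins the exchangeable
  # set, so P(p_ew <= alpha) = floor(alpha (B+1)) / (B+1) <= alpha under
  # the null -- the family-wise error is controlled at alpha exactly
  obs$significant <- obs$p_ew <= alpha

  list(terms = obs, critical = critical, max_f = max_f,
       n_perm = n_perm_eff, alpha = alpha)
}

# all combinations of per-environment permutations (exhaustive null)
.enumerate_within_env <- function(env_groups, limit = 100000L) {
  total <- prod(vapply(env_groups, function(g) factorial(length(g)), 0))
  if (total > limit) {
    stop("exhaustive enumeration would need ", format(total, scientific = FALSE),
         " permutations (limit ", limit, ")", call. = FALSE)
  }
  perm_list <- lapply(env_groups, function(g) .all_perms(length(g)))
  grids <- do.call(expand.grid, lapply(perm_list, seq_along))
  n <- sum(lengths(env_groups))
  lapply(seq_len(nrow(grids)), function(r) {
    idx <- seq_len(n)
    for (k in seq_along(env_groups)) {
      g <- env_groups[[k]]
      idx[g] <- g[perm_list[[k]][[grids[r, k]]]]
    }
    idx
  })
}

.all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(s, n, after = pos - 1L)
    }
  }
  out
}

#' Empirical experiment-wise type I error under the null
#'
#' Monte-Carlo experiment measuring the family-wise error rate of the
#' permutation-thresholded association scan: simulates replicate NAM-like
#' datasets with all genetic effects zero (phenotype = residual noise
#' within environments), runs the marginal Henderson-III scan with
#' within-environment permutation thresholds on every replicate, and
#' reports the fraction of replicates in which any term exceeds its
#' family's critical F.
#'
#' @param n_datasets number of replicate null datasets.
#' @param n_lines lines per dataset (split over \code{n_families}).
#' @param n_envs environments per dataset.
#' @param n_snps candidate SNPs per dataset.
#' @param n_perm permutations per dataset.
#' @param alpha nominal experiment-wise level.
#' @param seed integer seed; per-replicate seeds are derived via
#'   [split_seed()].
#' @param n_families families per dataset.
#' @param het_rate residual heterozygosity of the simulated genotypes.
#' @return list with \code{rate} (rejection fraction), \code{rejected}
#'   (logical per replicate), \code{se} (binomial standard error at the
#'   nominal level) and the experiment parameters.
#' @export
typeI_error_experiment <- function(n_datasets = 200L, n_lines = 500L,
                                   n_envs = 2L, n_snps = 50L,
                                   n_perm = 200L, alpha = 0.05, seed = 1L,
                                   n_families = 5L, het_rate = 0.03) {
  rejected <- vapply(seq_len(n_datasets), function(i) {
    g <- simulate_nam_genotypes(
      n_families, n_lines %/% n_families, n_snps,
      het_rate = het_rate, missing_rate = 0,
      seed = split_seed(seed, 1000L + i))
    arch <- genetic_architecture(
      mu = 0, loci = data.frame(snp = g$snps$snp[1], a = 0, d = 0),
      env_effects = rep(0, n_envs), residual_sd = 1)
    ph <- simulate_phenotypes(g, arch, n_envs = n_envs,
                              seed = split_seed(seed, 200000L + i))
    thr <- permutation_threshold(g, ph, g$snps$snp, n_perm = n_perm,
                                 alpha = alpha,
                                 seed = split_seed(seed, 400000L + i))
    any(thr$terms$significant)
  }, TRUE)
  list(rate = mean(rejected), rejected = rejected,
       se = sqrt(alpha * (1 - alpha) / n_datasets),
       n_datasets = n_datasets, n_perm = n_perm, alpha = alpha)
}
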