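#' Gibbs-sampling effect estimation for the full genetic model
#'
#' Draws from the joint posterior of the fitted model by Gibbs sampling:
#' flat priors on fixed effects, independent Normal(0, sigma_b^2) priors on
#' each random block's effects, and inverse-gamma(0.001, 0.001) priors on
#' every variance component including the residual.  Each iteration samples
#' all location coefficients jointly from their Gaussian full conditional
#' (via the mixed-model-equation Cholesky, so the cost per iteration does
#' not grow with the number of records) and then the variance components.
#' The chain is initialized at the REML solution.  Posterior means and
#' standard deviations of the fixed effects and of the realized
#' environment-specific interaction effects (ae, de, aae, ade, dae, dde)
#' are returned.
#'
#' If the model is numerically noiseless (residual variance below
#' \code{1e-10} times the response variance) the sampler is skipped and the
#' exact generalized-least-squares solution is returned with zero posterior
#' spread, with a message.
#'
#' A Geweke-style split-mean diagnostic (first 20\% vs last 50\% of the
#' kept draws) is computed for the residual variance and the first fixed
#' effects; a warning is issued when |z| > 4.
#'
#' @param fitted an \code{fgm_fit} from [fit_full_model()].
#' @param n_iter total Gibbs iterations (default 20000).
#' @param burn_in discarded initial iterations (default 2000).
#' @param thin keep every \code{thin}-th draw (default 5).
#' @param seed integer seed; the same seed reproduces the posterior
#'   summaries exactly.
#' @return object of class \code{effect_estimates}: data.frame with
#'   columns \code{term}, \code{type}, \code{estimate}, \code{sd}; variance
#'   component posterior summaries in \code{attr(, "vc")}; convergence
#'   diagnostics in \code{attr(, "diagnostics")}.
#' @export
gibbs_estimate <- function(fitted, n_iter = 20000L, burn_in = 2000L,
                           thin = 5L, seed = 1L) {
  stopifnot(inherits(fitted, "fgm_fit"))
  n_iter <- .check_count(n_iter, "n_iter")
  burn_in <- .check_count(burn_in, "burn_in", min = 0L)
  thin <- .check_count(thin, "thin")
  if (n_iter <= burn_in) stop("`n_iter` must exceed `burn_in`", call. = FALSE)

  dm <- fitted$design
  y <- fitted$y
  n <- length(y)
  Xf <- cbind(`(Intercept)` = 1, dm$C, dm$X)
  X <- Xf[, names(fitted$beta), drop = FALSE]
  Zb <- dm$Z[intersect(names(dm$Z), fitted$vc$block)]
  Z <- if (length(Zb) > 0L) do.call(cbind, Zb) else NULL
  W <- if (is.null(Z)) X else cbind(X, Z)
  p <- ncol(X)
  qb <- vapply(Zb, ncol, 0L)
  block_of <- rep(seq_along(Zb), qb)

  WtW <- crossprod(W)
  Wty <- drop(crossprod(W, y))
  yty <- sum(y * y)

  resid_var0 <- fitted$vc$sigma2[fitted$vc$block == "residual"]
  if (resid_var0 < 1e-10 * max(yty / n, 1)) {
    message("residual variance is numerically zero; returning the exact solution")
    theta <- c(fitted$beta, unlist(fitted$blup, use.names = FALSE))
    return(.effects_table(fitted, theta, theta * 0,
                          vc_summary = data.frame(
                            block = fitted$vc$block, mean = fitted$vc$sigma2,
                            sd = 0), diagnostics = NULL))
  }

  a0 <- b0 <- 0.001
  sigma2_b <- fitted$vc$sigma2[match(names(Zb), fitted$vc$block)]
  sigma2_b <- pmax(sigma2_b, 1e-8)
  sigma2_e <- resid_var0
  theta <- c(fitted$beta, unlist(fitted$blup, use.names = FALSE))
  theta[!is.finite(theta)] <- 0

  # Hierarchical recentering for identifiability: the environment columns
  # sum to the intercept column and each term's masked interaction columns
  # sum to the term's fixed column, so after every draw the mean of each
  # such group is moved into its parent coefficient.  The likelihood is
  # unchanged and the interaction effects are reported as pure deviations
  # (the same centered parameterization the architecture uses).
  theta_names <- colnames(W)
  recenter <- list()
  int_idx <- match("(Intercept)", theta_names)
  env_idx <- which(grepl("^env[0-9]+$", theta_names))
  if (!is.na(int_idx) && length(env_idx) > 0L) {
    recenter[[length(recenter) + 1L]] <- list(idx = env_idx, target = int_idx)
  }
  gxe_fixed <- c(ae = "a", de = "d", aae = "aa", ade = "ad",
                 dae = "da", dde = "dd")
  gxe_cols <- grep("^(ae|de|aae|ade|dae|dde)@", theta_names)
  if (length(gxe_cols) > 0L) {
    key <- sub(":env[0-9]+$", "", theta_names[gxe_cols])
    for (grp in split(gxe_cols, key)) {
      nm <- sub(":env[0-9]+$", "", theta_names[grp[1L]])
      pre <- sub("@.*$", "", nm)
      fixed_nm <- paste0(gxe_fixed[pre], "@", sub("^[a-z]+@", "", nm))
      tgt <- match(fixed_nm, theta_names)
      if (!is.na(tgt)) {
        recenter[[length(recenter) + 1L]] <- list(idx = grp, target = tgt)
      }
    }
  }
  apply_recenter <- function(theta) {
    for (rc in recenter) {
      m <- mean(theta[rc$idx])
      theta[rc$idx] <- theta[rc$idx] - m
      theta[rc$target] <- theta[rc$target] + m
    }
    theta
  }

  keep_iters <- seq.int(burn_in + thin, n_iter, by = thin)
  n_keep <- length(keep_iters)
  draws <- matrix(NA_real_, n_keep, length(theta))
  vc_draws <- matrix(NA_real_, n_keep, length(Zb) + 1L)
  k <- 0L

  # variance draws are capped so a weakly informed block cannot send the
  # joint precision matrix numerically singular (flat-prior fixed columns
  # duplicated by a nearly-unpenalized one-column block)
  s2_cap <- 1e6 * max(yty / n, 1)
  ridge <- 1e-8 * max(diag(WtW))

  withr::with_seed(seed, {
    for (it in seq_len(n_iter)) {
      prior_prec <- c(rep(0, p), rep(1 / sigma2_b, qb))
      Cmat <- WtW / sigma2_e
      diag(Cmat) <- diag(Cmat) + prior_prec + ridge / sigma2_e
      R <- chol(Cmat)
      m <- backsolve(R, forwardsolve(t(R), Wty / sigma2_e))
      theta <- apply_recenter(drop(m + backsolve(R, rnorm(length(m)))))

      if (length(Zb) > 0L) {
        for (b in seq_along(Zb)) {
          ub <- theta[p + which(block_of == b)]
          sigma2_b[b] <- min(1 / rgamma(1L, a0 + length(ub) / 2,
                                        b0 + sum(ub^2) / 2), s2_cap)
        }
      }
      rss <- yty - 2 * sum(theta * Wty) + drop(crossprod(theta, WtW %*% theta))
      rss <- max(rss, 0)
      sigma2_e <- 1 / rgamma(1L, a0 + n / 2, b0 + rss / 2)

      if (it %in% keep_iters) {
        k <- k + 1L
        draws[k, ] <- theta
        vc_draws[k, ] <- c(sigma2_b, sigma2_e)
      }
    }
  })

  post_mean <- colMeans(draws)
  post_sd <- apply(draws, 2L, sd)
  vc_summary <- data.frame(
    block = c(names(Zb), "residual"),
    mean = colMeans(vc_draws),
    sd = apply(vc_draws, 2L, sd),
    stringsAsFactors = FALSE
  )

  geweke_z <- function(x) {
    n1 <- max(2L, floor(0.2 * length(x)))
    n2 <- max(2L, floor(0.5 * length(x)))
    x1 <- x[seq_len(n1)]; x2 <- x[seq.int(length(x) - n2 + 1L, length(x))]
    (mean(x1) - mean(x2)) / sqrt(var(x1) / n1 + var(x2) / n2)
  }
  diag_terms <- c(seq_len(min(3L, p)))
  zs <- c(sigma2_resid = geweke_z(vc_draws[, ncol(vc_draws)]),
          setNames(vapply(diag_terms, function(j) geweke_z(draws[, j]), 0),
                   names(fitted$beta)[diag_terms]))
  if (any(abs(zs) > 4, na.rm = TRUE)) {
    warning("Gibbs chain may not have converged (|Geweke z| > 4 for: ",
            paste(names(zs)[abs(zs) > 4], collapse = ", "), ")", call. = FALSE)
  }

  .effects_table(fitted, post_mean, post_sd, vc_summary,
                 diagnostics = list(geweke_z = zs, n_kept = n_keep))
}

# assemble the effect-estimate table from a coefficient vector
.effects_table <- function(fitted, est, sds, vc_summary, diagnostics) {
  dm <- fitted$design
  fixed_names <- names(fitted$beta)
  Zb <- dm$Z[intersect(names(dm$Z), fitted$vc$block)]
  rand_names <- unlist(lapply(Zb, colnames), use.names = FALSE)
  terms <- c(fixed_names, rand_names)
  type <- sub("@.*$", "", terms)
  type[terms == "(Intercept)"] <- "mu"
  type[grepl("^PC", terms)] <- "pc"
  type[grepl("^env", terms)] <- "env"
  out <- data.frame(term = terms, type = type,
                    estimate = est, sd = sds, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, vc = vc_summary, diagnostics = diagnostics,
            pruned = fitted$pruned,
            class = c("effect_estimates", "data.frame"))
}

#' Convert estimated effects into a genetic architecture
#'
#' Maps the posterior means of an [gibbs_estimate()] result back into a
#' [genetic_architecture()] (effect set) usable by the breeding module.
#' Terms pruned from the model are treated as zero.  Optionally only
#' terms declared significant (e.g. surviving the experiment-wise
#' threshold) are retained.
#'
#' @param estimates an \code{effect_estimates}.
#' @param dm the matching \code{design_matrices}.
#' @param keep_terms optional character vector of term ids to keep (others
#'   zeroed); NULL keeps everything.
#' @return a [genetic_architecture()] (residual_sd from the posterior
#'   residual variance; mean from the intercept).
#' @export
effects_to_architecture <- function(estimates, dm, keep_terms = NULL) {
  est <- setNames(estimates$estimate, estimates$term)
  if (!is.null(keep_terms)) {
    zero <- !(names(est) %in% c(keep_terms, "(Intercept)")) &
      !estimates$type %in% c("env", "pc", "mu")
    est[zero] <- 0
  }
  get1 <- function(nm) if (nm %in% names(est)) unname(est[nm]) else 0
  loci <- data.frame(
    snp = dm$loci,
    a = vapply(paste0("a@", dm$loci), get1, 0),
    d = vapply(paste0("d@", dm$loci), get1, 0),
    stringsAsFactors = FALSE
  )
  pairs <- NULL
  pn <- character(0)
  if (nrow(dm$pairs) > 0L) {
    pn <- paste(dm$pairs$snp1, dm$pairs$snp2, sep = "x")
    pairs <- data.frame(
      snp1 = dm$pairs$snp1, snp2 = dm$pairs$snp2,
      aa = vapply(paste0("aa@", pn), get1, 0),
      ad = vapply(paste0("ad@", pn), get1, 0),
      da = vapply(paste0("da@", pn), get1, 0),
      dd = vapply(paste0("dd@", pn), get1, 0),
      stringsAsFactors = FALSE
    )
  }
  envs <- dm$envs
  env_eff <- vapply(paste0("env", envs), get1, 0)
  gxe_mat <- function(prefix, ids) {
    if (length(ids) == 0L) return(NULL)
    m <- outer(ids, envs, function(i, h) {
      vapply(paste0(prefix, "@", i, ":env", h), get1, 0)
    })
    if (all(m == 0)) return(NULL)
    m
  }
  vc <- attr(estimates, "vc")
  resid_sd <- if (!is.null(vc)) sqrt(max(vc$mean[vc$block == "residual"], 0)) else 1
  genetic_architecture(
    mu = get1("(Intercept)"), loci = loci, pairs = pairs,
    env_effects = env_eff,
    ae = gxe_mat("ae", dm$loci), de = gxe_mat("de", dm$loci),
    aae = gxe_mat("aae", pn), ade = gxe_mat("ade", pn),
    dae = gxe_mat("dae", pn), dde = gxe_mat("dde", pn),
    residual_sd = max(resid_sd, .Machine$double.eps)
  )
}
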