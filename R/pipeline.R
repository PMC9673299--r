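#' Default run configuration
#'
#' Returns the default configuration for [run_pipeline()].  Defaults
#' mirror the standard analysis settings: MAF cutoff 0.05, call-rate
#' cutoff 0.90, IQR fence multiplier 1.5, residual cutoff 3, 2000
#' permutations at alpha 0.05 and 20000 Gibbs iterations.  Any field can
#' be overridden by the supplied list or YAML file.
#'
#' @param ... named overrides merged over the defaults (nested lists are
#'   merged one level deep).
#' @return a named list of class \code{run_config}.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = list(n_families = 10L, lines_per_family = 100L, n_snps = 200L,
                    het_rate = 0.03, missing_rate = 0.01, n_envs = 2L,
                    n_causal = 4L, n_pairs = 1L,
                    target_h2 = c(A = 0.10, D = 0.05, AE = 0.05)),
    geno_path = NULL, geno_format = "hapmap", pheno_path = NULL,
    qc = list(maf_min = 0.05, call_rate_min = 0.90, iqr_k = 1.5, resid_k = 3),
    prescreen = list(dims = c(1L, 2L), top_k = 10L, n_folds = 5L,
                     survivors = 15L),
    model = list(n_pcs = 0L, n_perm = 2000L, alpha = 0.05,
                 n_iter = 20000L, burn_in = 2000L, thin = 5L),
    breeding = list(enumerate_limit = 20000L)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      for (sub in names(over[[nm]])) cfg[[nm]][[sub]] <- over[[nm]][[sub]]
    } else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' @param cfg a \code{run_config} (list).
#' @return the validated config, invisibly; errors on invalid fields.
#' @export
validate_config <- function(cfg) {
  .check_fraction(cfg$qc$maf_min, "qc$maf_min", hi_open = FALSE)
  .check_fraction(cfg$qc$call_rate_min, "qc$call_rate_min", hi_open = FALSE)
  if (cfg$qc$iqr_k < 0) stop("qc$iqr_k must be >= 0", call. = FALSE)
  if (cfg$qc$resid_k <= 0) stop("qc$resid_k must be > 0", call. = FALSE)
  .check_fraction(cfg$model$alpha, "model$alpha", hi_open = FALSE)
  .check_count(cfg$model$n_perm, "model$n_perm")
  .check_count(cfg$model$n_iter, "model$n_iter")
  .check_count(cfg$seed, "seed", min = 0L)
  if (!all(cfg$prescreen$dims %in% 1:3)) {
    stop("prescreen$dims must be a subset of {1, 2, 3}", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; fields override [default_config()].
#' @return a validated \code{run_config}.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate$target_h2)) {
    raw$simulate$target_h2 <- unlist(raw$simulate$target_h2)
  }
  validate_config(do.call(default_config, raw))
}

# stable short hash of the configuration for output provenance
.config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(unclass(cfg)))]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage: data simulation (or file ingest), quality
#' control, GMDR prescreening, mixed-model association with permutation
#' thresholds, Gibbs effect estimation, heritability partitioning and
#' breeding prediction.  Each stage derives its own seed from the
#' run-level seed via [split_seed()] so reruns with the same config are
#' reproducible; every output table carries the config hash and seed in a
#' header comment, and a log file records stage progress.
#'
#' @param config a \code{run_config} (see [default_config()],
#'   [read_run_config()]).
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the main stage results (\code{geno},
#'   \code{pheno}, \code{candidates}, \code{threshold}, \code{fit},
#'   \code{estimates}, \code{heritability}, \code{breeding}) and
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("nampipe")) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    cat(line, "\n", file = log_path, append = TRUE)
    message(line)
  }
  stamp <- function(path) {
    # prepend provenance header; outputs are pure functions of (config, seed)
    txt <- readLines(path)
    writeLines(c(sprintf("# config_hash=%s seed=%d", hash, config$seed), txt), path)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  logf("init", sprintf("config hash %s, seed %d", hash, config$seed))

  # --- data -----------------------------------------------------------------
  res <- run_stage("data", {
    if (!is.null(config$geno_path)) {
      geno <- read_genotypes(config$geno_path, config$geno_format)
      pheno <- read_phenotypes(config$pheno_path)
      list(geno = geno, pheno = pheno, arch = NULL)
    } else {
      sim <- config$simulate
      geno <- simulate_nam_genotypes(
        sim$n_families, sim$lines_per_family, sim$n_snps,
        het_rate = sim$het_rate, missing_rate = sim$missing_rate,
        seed = split_seed(config$seed, 1L))
      arch <- make_architecture(
        n_loci = sim$n_causal, n_pairs = sim$n_pairs,
        target_h2 = sim$target_h2, seed = split_seed(config$seed, 2L),
        n_envs = sim$n_envs, ref_geno = geno)
      pheno <- simulate_phenotypes(geno, arch, n_envs = sim$n_envs,
                                   seed = split_seed(config$seed, 3L))
      list(geno = geno, pheno = pheno, arch = arch)
    }
  })
  geno <- res$geno; pheno <- res$pheno
  write_genotypes_hapmap(geno, file.path(out_dir, "genotypes.hmp.tsv"))
  write_phenotypes_csv(pheno, file.path(out_dir, "phenotypes.csv"))
  logf("data", sprintf("%d lines x %d SNPs, %d phenotype records",
                       nrow(geno$codes), ncol(geno$codes), nrow(pheno)))

  # --- QC -------------------------------------------------------------------
  qc <- run_stage("qc", {
    fs <- filter_snps(geno, config$qc$maf_min, config$qc$call_rate_min)
    iqr <- remove_phenotype_outliers_iqr(pheno, config$qc$iqr_k)
    res <- remove_residual_outliers(iqr$pheno, config$qc$resid_k)
    list(geno = fs$geno, pheno = res$pheno,
         reports = list(fs$report, iqr$report, res$report))
  })
  geno <- qc$geno; pheno <- qc$pheno
  write_qc_report(qc$reports[[1]], file.path(out_dir, "qc_snps.tsv"))
  write_qc_report(qc$reports[[2]], file.path(out_dir, "qc_iqr.tsv"))
  write_qc_report(qc$reports[[3]], file.path(out_dir, "qc_residual.tsv"))
  logf("qc", sprintf("%d SNPs and %d records retained",
                     ncol(geno$codes), nrow(pheno)))

  # --- prescreen ------------------------------------------------------------
  cand <- run_stage("prescreen", {
    gmdr_scan(pheno, geno, dims = config$prescreen$dims,
              top_k = config$prescreen$top_k,
              n_folds = config$prescreen$n_folds,
              survivors = config$prescreen$survivors,
              seed = split_seed(config$seed, 4L))
  })
  write_candidate_set(cand, file.path(out_dir, "candidates.tsv"))
  terms <- candidate_terms(cand)
  logf("prescreen", sprintf("%d candidate loci, %d pairs",
                            length(terms$loci), nrow(terms$pairs)))

  # --- association ----------------------------------------------------------
  thr <- run_stage("assoc", {
    permutation_threshold(geno, pheno, terms$loci, terms$pairs,
                          n_perm = config$model$n_perm,
                          alpha = config$model$alpha,
                          seed = split_seed(config$seed, 5L),
                          n_pcs = config$model$n_pcs)
  })
  write.table(thr$terms, file.path(out_dir, "scan.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  stamp(file.path(out_dir, "scan.tsv"))
  sig_terms <- thr$terms$term[thr$terms$significant]
  sig_loci <- unique(sub("^[a-z]+@", "",
                         grep("^(a|d)@", sig_terms, value = TRUE)))
  sig_pair_ids <- unique(sub("^[a-z]+@", "",
                             grep("^(aa|ad|da|dd)@", sig_terms, value = TRUE)))
  sig_pairs <- if (length(sig_pair_ids) > 0L) {
    parts <- strsplit(sig_pair_ids, "x", fixed = TRUE)
    data.frame(snp1 = vapply(parts, `[`, "", 1L),
               snp2 = vapply(parts, `[`, "", 2L), stringsAsFactors = FALSE)
  } else NULL
  if (!is.null(sig_pairs)) {
    sig_loci <- union(sig_loci, c(sig_pairs$snp1, sig_pairs$snp2))
  }
  logf("assoc", sprintf("%d significant terms (%d loci, %d pairs) at alpha %.3g",
                        length(sig_terms), length(sig_loci),
                        if (is.null(sig_pairs)) 0L else nrow(sig_pairs),
                        config$model$alpha))
  if (length(sig_loci) == 0L) {
    logf("assoc", "no term survived the experiment-wise threshold; stopping")
    out <- list(geno = geno, pheno = pheno, candidates = cand, threshold = thr,
                fit = NULL, estimates = NULL, heritability = NULL,
                breeding = NULL, out_dir = out_dir, truth = res$arch)
    return(invisible(out))
  }

  fitres <- run_stage("estimate", {
    dm <- build_design(geno, pheno, sig_loci, sig_pairs,
                       n_pcs = config$model$n_pcs)
    fit <- fit_full_model(dm)
    est <- gibbs_estimate(fit, n_iter = config$model$n_iter,
                          burn_in = config$model$burn_in,
                          thin = config$model$thin,
                          seed = split_seed(config$seed, 6L))
    list(dm = dm, fit = fit, est = est)
  })
  write.table(fitres$est, file.path(out_dir, "effects.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  stamp(file.path(out_dir, "effects.tsv"))
  write.table(per_env_effects(fitres$est, fitres$dm),
              file.path(out_dir, "effects_per_env.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  logf("estimate", sprintf("%d effect estimates", nrow(fitres$est)))

  # --- heritability ---------------------------------------------------------
  ht <- run_stage("herit", heritability(fitres$est, fitres$dm))
  write_herit_table(ht, file.path(out_dir, "heritability.tsv"))
  stamp(file.path(out_dir, "heritability.tsv"))
  agg <- attr(ht, "aggregates")
  logf("herit", sprintf("h2_T = %.2f%%, h2_D+ = %.2f%%, h2_GE = %.2f%%",
                        agg[1], agg[2], agg[3]))

  # --- breeding -------------------------------------------------------------
  breeding <- run_stage("breed", {
    eff <- effects_to_architecture(fitres$est, fitres$dm)
    predict_breeding_table(eff, geno,
                           enumerate_limit = config$breeding$enumerate_limit)
  })
  write_breeding_table(breeding, file.path(out_dir, "breeding.tsv"))
  stamp(file.path(out_dir, "breeding.tsv"))
  logf("breed", "breeding table written")

  invisible(list(geno = geno, pheno = pheno, candidates = cand,
                 threshold = thr, fit = fitres$fit, estimates = fitres$est,
                 heritability = ht, breeding = breeding, out_dir = out_dir,
                 truth = res$arch))
}

#' Packaged demonstration fixtures
#'
#' Seeded, documented datasets used across the test suite and examples:
#' \describe{
#'   \item{null}{all genetic effects zero: phenotype = mean + environment +
#'     noise.}
#'   \item{additive}{four additive loci, no dominance or interactions.}
#'   \item{epistatic}{main effects plus an aa and a dd pair.}
#'   \item{gxe}{two loci whose additive effects flip sign between two
#'     environments (environment-specific deviations dominate).}
#'   \item{trait-profile}{component shares patterned on a published maize
#'     ear-trait profile (A 10\%, D 9\%, AE 12\%, DE 5\%).}
#' }
#'
#' @param name one of \code{"null"}, \code{"additive"}, \code{"epistatic"},
#'   \code{"gxe"}, \code{"trait-profile"}.
#' @param n_families,lines_per_family,n_snps population dimensions.
#' @param seed integer seed.
#' @return list with \code{geno}, \code{arch}, \code{pheno}.
#' @export
make_fixture <- function(name, n_families = 5L, lines_per_family = 60L,
                         n_snps = 40L, seed = 1L) {
  fixtures <- c("null", "additive", "epistatic", "gxe", "trait-profile")
  if (!name %in% fixtures) {
    stop("unknown fixture '", name, "'; valid fixtures: ",
         paste(fixtures, collapse = ", "), call. = FALSE)
  }
  geno <- simulate_nam_genotypes(n_families, lines_per_family, n_snps,
                                 het_rate = 0.05, missing_rate = 0,
                                 seed = split_seed(seed, 21L))
  loci <- geno$snps$snp[1:4]
  n_envs <- 2L
  arch <- switch(
    name,
    "null" = genetic_architecture(
      mu = 10, loci = data.frame(snp = loci, a = 0, d = 0),
      env_effects = c(0.5, -0.5), residual_sd = 1),
    "additive" = genetic_architecture(
      mu = 10, loci = data.frame(snp = loci, a = c(1, 0.8, -0.6, 0.4), d = 0),
      env_effects = c(0.5, -0.5), residual_sd = 1),
    "epistatic" = genetic_architecture(
      mu = 10, loci = data.frame(snp = loci, a = c(0.8, 0.6, 0.3, 0.3),
                                 d = c(0.5, 0, 0, 0)),
      pairs = data.frame(snp1 = loci[c(1, 3)], snp2 = loci[c(2, 4)],
                         aa = c(0.8, 0), ad = 0, da = 0, dd = c(0, 2.5)),
      env_effects = c(0.5, -0.5), residual_sd = 1),
    "gxe" = genetic_architecture(
      mu = 10, loci = data.frame(snp = loci, a = c(0.2, -0.1, 0, 0), d = 0),
      env_effects = c(0.5, -0.5),
      ae = rbind(c(1.2, -1.2), c(-0.9, 0.9), c(0, 0), c(0, 0)),
      residual_sd = 1),
    "trait-profile" = make_architecture(
      n_loci = 4L, n_pairs = 0L,
      target_h2 = c(A = 0.10, D = 0.09, AE = 0.12, DE = 0.05),
      seed = split_seed(seed, 22L), n_envs = n_envs, ref_geno = geno, mu = 10)
  )
  pheno <- simulate_phenotypes(geno, arch, n_envs = n_envs,
                               seed = split_seed(seed, 23L))
  list(geno = geno, arch = arch, pheno = pheno)
}
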