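test_that("noiseless single-locus data recovers the additive effect exactly", {
  g <- balanced_locus_geno(12)
  arch <- toy_arch("S1_1000", a = 1.7, d = 0.4, mu = 3,
                   residual_sd = .Machine$double.eps)
  ph <- simulate_phenotypes(g, arch, n_envs = 1, seed = 1)
  dm <- build_design(g, ph, "S1_1000")
  fit <- fit_full_model(dm)
  expect_equal(unname(fit$beta["a@S1_1000"]), 1.7, tolerance = 1e-9)
  expect_equal(unname(fit$beta["d@S1_1000"]), 0.4, tolerance = 1e-9)
})

test_that("joint Henderson-III F equals the classical one-way ANOVA F", {
  g <- balanced_locus_geno(15)
  y <- withr::with_seed(2, rnorm(45) + rep(c(1, 2, 0.5), each = 15))
  ph <- toy_pheno(g$lines, y)
  dm <- build_design(g, ph, "S1_1000")
  hf <- henderson_f(dm, c("a@S1_1000", "d@S1_1000"), y = y)
  oracle <- anova(lm(y ~ factor(rep(c("QQ", "Qq", "qq"), each = 15))))
  expect_equal(hf$F, oracle$`F value`[1], tolerance = 1e-10)
  expect_equal(hf$df1, oracle$Df[1])
  expect_equal(hf$p, oracle$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("terms with all-zero coefficients give F = 0", {
  codes <- matrix(rep("QQ", 20), ncol = 1,
                  dimnames = list(sprintf("L%02d", 1:20), "S1_1000"))
  g <- toy_geno(codes)
  ph <- toy_pheno(g$lines, withr::with_seed(3, rnorm(20)))
  dm <- build_design(g, ph, "S1_1000")
  hf <- henderson_f(dm, "d@S1_1000")    # no heterozygotes: x_D all zero
  expect_equal(hf$F, 0)
  expect_equal(hf$p, 1)
})

test_that("pointwise P-values are uniform under the null", {
  ps <- withr::with_seed(11, {
    unlist(lapply(1:80, function(rep) {
      g <- simulate_nam_genotypes(4, 50, 5, het_rate = 0.2, missing_rate = 0,
                                  seed = 1000 + rep)
      ph <- toy_pheno(g$lines, rnorm(200))
      tab <- henderson_scan(g, ph, g$snps$snp)
      tab$p[tab$type == "a"]
    }))
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("an interaction-only architecture loads the AE variance component", {
  g <- simulate_nam_genotypes(4, 100, 2, het_rate = 0.05, missing_rate = 0,
                              seed = 13)
  arch <- toy_arch(g$snps$snp[1:2], a = 0, d = 0, env_effects = c(0, 0),
                   ae = rbind(c(-2, 2), c(0, 0)), residual_sd = 1)
  ph <- simulate_phenotypes(g, arch, n_envs = 2, seed = 14)
  dm <- build_design(g, ph, arch$loci$snp)
  fit <- fit_full_model(dm)
  vc <- setNames(fit$vc$sigma2, fit$vc$block)
  expect_gt(vc["AE"], 0.5)
  nm <- paste0("a@", arch$loci$snp[1])
  expect_lt(abs(fit$beta[nm]), 4 * fit$se[nm])
})

test_that("an empty fixed block reduces to environment means", {
  g <- simulate_nam_genotypes(2, 30, 2, seed = 15)
  arch <- toy_arch(g$snps$snp[1], a = 0, env_effects = c(1, -1))
  ph <- simulate_phenotypes(g, arch, n_envs = 2, seed = 16)
  dm <- build_design(g, ph, character(0))
  expect_equal(ncol(dm$X), 0L)
  fit <- fit_full_model(dm)
  mu_by_env <- unname(fit$beta["(Intercept)"]) +
    unlist(fit$blup[["env"]], use.names = FALSE)
  expect_equal(sort(unname(mu_by_env)),
               sort(as.vector(tapply(ph$value, ph$env, mean))),
               tolerance = 0.05)
})

test_that("the marginal scan agrees with per-locus Henderson reductions", {
  g <- simulate_nam_genotypes(3, 40, 4, het_rate = 0.25, missing_rate = 0,
                              seed = 17)
  arch <- toy_arch(g$snps$snp[1], a = 1, d = 0.5, env_effects = c(0.5, -0.5))
  ph <- simulate_phenotypes(g, arch, n_envs = 2, seed = 18)
  tab <- henderson_scan(g, ph, g$snps$snp)
  for (s in g$snps$snp[1:2]) {
    dm1 <- build_design(g, ph, s)
    dm1$Z <- dm1$Z["env"]  # marginal scan models env + a + d only
    for (tt in c("a", "d")) {
      hf <- henderson_f(dm1, paste0(tt, "@", s))
      row <- tab[tab$term == paste0(tt, "@", s), ]
      expect_equal(row$F, hf$F, tolerance = 1e-8)
      expect_equal(row$df1, hf$df1)
    }
  }
})

test_that("the scan detects epistasis terms for a planted dd pair", {
  g <- simulate_nam_genotypes(4, 150, 4, het_rate = 0.4, missing_rate = 0,
                              seed = 19)
  arch <- genetic_architecture(
    loci = data.frame(snp = g$snps$snp[1:2], a = 0, d = 0),
    pairs = data.frame(snp1 = g$snps$snp[1], snp2 = g$snps$snp[2],
                       aa = 0, ad = 0, da = 0, dd = 3),
    residual_sd = 1)
  ph <- simulate_phenotypes(g, arch, n_envs = 1, seed = 20)
  tab <- henderson_scan(g, ph, g$snps$snp[1:2],
                        pairs = data.frame(snp1 = g$snps$snp[1],
                                           snp2 = g$snps$snp[2]))
  dd_row <- tab[tab$type == "dd", ]
  expect_gt(dd_row$neg_log10_p, 5)
  expect_equal(dd_row$family, "epistasis")
})
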