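test_that("genotype simulation is deterministic and respects het_rate = 0", {
  g1 <- simulate_nam_genotypes(2, 10, 5, het_rate = 0, missing_rate = 0, seed = 1)
  g2 <- simulate_nam_genotypes(2, 10, 5, het_rate = 0, missing_rate = 0, seed = 1)
  expect_identical(g1$codes, g2$codes)
  expect_equal(dim(g1$codes), c(20L, 5L))
  expect_true(all(g1$codes %in% c("QQ", "qq")))

  g3 <- simulate_nam_genotypes(2, 10, 5, het_rate = 0, missing_rate = 0, seed = 2)
  expect_false(identical(g1$codes, g3$codes))
})

test_that("heterozygote fraction matches the injection rate", {
  g <- simulate_nam_genotypes(25, 200, 1000, het_rate = 0.03,
                              missing_rate = 0, seed = 7)
  n_cells <- length(g$codes)
  phat <- mean(g$codes == "Qq")
  se <- sqrt(0.03 * 0.97 / n_cells)
  expect_lt(abs(phat - 0.03), 3 * se)
})

test_that("missing calls appear at the requested rate and parse as NA", {
  g <- simulate_nam_genotypes(5, 100, 50, het_rate = 0, missing_rate = 0.1,
                              seed = 3)
  phat <- mean(is.na(g$codes))
  expect_lt(abs(phat - 0.1), 3 * sqrt(0.1 * 0.9 / length(g$codes)))
})

test_that("segregating SNPs have B73-allele frequency near 0.5 within family", {
  g <- simulate_nam_genotypes(4, 500, 50, het_rate = 0, missing_rate = 0,
                              seed = 5)
  fam <- g$families
  for (f in unique(fam)) {
    sub <- g$codes[fam == f, , drop = FALSE]
    seg <- apply(sub, 2, function(col) any(col == "QQ") && any(col == "qq"))
    freq_qq <- colMeans(sub[, seg, drop = FALSE] == "qq")
    # binomial spread around 0.5 at n = 500 lines
    expect_true(all(abs(freq_qq - 0.5) < 5 * sqrt(0.25 / nrow(sub))))
  }
})

test_that("null architecture yields exactly the mean, zero-noise limit", {
  g <- simulate_nam_genotypes(2, 20, 4, het_rate = 0, missing_rate = 0, seed = 1)
  arch <- toy_arch(g$snps$snp[1:2], a = 0, d = 0, mu = 5,
                   residual_sd = .Machine$double.eps)
  ph <- simulate_phenotypes(g, arch, n_envs = 1, seed = 9)
  expect_equal(ph$value, rep(5, nrow(ph)), tolerance = 1e-10)
})

test_that("single additive locus shifts the two homozygote classes by +/- a", {
  codes <- matrix(rep(c("QQ", "qq"), each = 5), ncol = 1,
                  dimnames = list(sprintf("Z01E%04d", 1:10), "S1_1000"))
  g <- toy_geno(codes)
  arch <- toy_arch("S1_1000", a = 2, mu = 10,
                   residual_sd = .Machine$double.eps)
  ph <- simulate_phenotypes(g, arch, n_envs = 1, seed = 1)
  expect_equal(ph$value[1:5], rep(12, 5), tolerance = 1e-9)
  expect_equal(ph$value[6:10], rep(8, 5), tolerance = 1e-9)
})

test_that("phenotypic variance matches the plug-in additive variance", {
  g <- simulate_nam_genotypes(10, 200, 5, het_rate = 0, missing_rate = 0,
                              seed = 11)
  arch <- toy_arch(g$snps$snp[1], a = 1, residual_sd = 1)
  ph <- simulate_phenotypes(g, arch, n_envs = 1, seed = 12)
  xA <- locus_coefficients(g, g$snps$snp[1])$xA[, 1]
  expected <- var(xA) + 1  # a^2 var(x_A) + sigma^2 with a = 1
  expect_lt(abs(var(ph$value) - expected), 0.15)
})

test_that("all-zero effects leave only residual variance", {
  g <- simulate_nam_genotypes(25, 200, 4, het_rate = 0, missing_rate = 0,
                              seed = 13)
  arch <- toy_arch(g$snps$snp[1:2], a = 0, d = 0, residual_sd = 1)
  ph <- simulate_phenotypes(g, arch, n_envs = 1, seed = 14)
  n <- nrow(ph)
  # chi-square bounds on the sample variance of N(0,1) at n = 5000
  expect_gt(var(ph$value), qchisq(0.0005, n - 1) / (n - 1))
  expect_lt(var(ph$value), qchisq(0.9995, n - 1) / (n - 1))
})

test_that("adding one fixed term only moves lines with nonzero coefficient", {
  g <- simulate_nam_genotypes(3, 30, 4, het_rate = 0.2, missing_rate = 0,
                              seed = 15)
  base <- toy_arch(g$snps$snp[1], a = 0, d = 0,
                   residual_sd = .Machine$double.eps)
  plus_d <- toy_arch(g$snps$snp[1], a = 0, d = 1.5,
                     residual_sd = .Machine$double.eps)
  p0 <- simulate_phenotypes(g, base, n_envs = 1, seed = 16)
  p1 <- simulate_phenotypes(g, plus_d, n_envs = 1, seed = 16)
  het <- g$codes[match(p0$line, g$lines), 1] == "Qq"
  expect_equal(p1$value[!het], p0$value[!het], tolerance = 1e-9)
  expect_equal(p1$value[het], p0$value[het] + 1.5, tolerance = 1e-9)
})

test_that("family means separate under family-confounded effects", {
  g <- simulate_nam_genotypes(5, 100, 30, het_rate = 0, missing_rate = 0,
                              seed = 17)
  arch <- toy_arch(g$snps$snp[1:5], a = c(2, 2, -2, 2, -2), residual_sd = 1)
  ph <- simulate_phenotypes(g, arch, n_envs = 1, seed = 18)
  fit <- anova(lm(value ~ family, data = ph))
  expect_lt(fit$`Pr(>F)`[1], 1e-4)
})

test_that("make_architecture hits a single-component target share", {
  arch <- make_architecture(5, 0, c(A = 0.10), seed = 3, n_envs = 2)
  g <- attr(arch, "ref_geno")
  ph <- simulate_phenotypes(g, arch, n_envs = 2, seed = 4)
  xA <- locus_coefficients(g, arch$loci$snp)$xA
  contrib <- drop(xA %*% arch$loci$a)
  realized <- var(rep(contrib, 2)) / var(ph$value)
  expect_lt(abs(realized - 0.10), 0.02)
})

test_that("make_architecture validates targets", {
  expect_error(make_architecture(5, 0, c(A = 0.6, D = 0.5), seed = 1),
               "sum to < 1")
  arch0 <- make_architecture(4, 1, c(A = 0), seed = 2, n_envs = 2)
  expect_true(all(arch0$loci$a == 0))
  expect_true(all(arch0$loci$d == 0))
  expect_true(all(arch0$pairs$aa == 0))
  expect_error(make_architecture(3, 0, c(AA = 0.1), seed = 1), "n_pairs")
})

test_that("simulation rejects invalid arguments and unknown loci", {
  expect_error(simulate_nam_genotypes(0, 10, 5), "n_families")
  expect_error(simulate_nam_genotypes(2, 10, 5, het_rate = 1), "het_rate")
  g <- simulate_nam_genotypes(2, 10, 5, seed = 1)
  arch <- toy_arch("S99_123", a = 1)
  expect_error(simulate_phenotypes(g, arch, n_envs = 1), "absent")
})
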