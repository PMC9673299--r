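test_that("genotypic values evaluate the model by hand", {
  arch <- genetic_architecture(
    loci = data.frame(snp = c("S1_1", "S2_1"), a = c(1, 2), d = 0),
    pairs = data.frame(snp1 = "S1_1", snp2 = "S2_1",
                       aa = 0.5, ad = 0, da = 0, dd = 0))
  expect_equal(genotypic_value(c(S1_1 = "QQ", S2_1 = "qq"), arch), -1.5)
  arch0 <- toy_arch(c("S1_1", "S2_1"), a = 0, d = 0)
  expect_equal(genotypic_value(c(S1_1 = "Qq", S2_1 = "QQ"), arch0), 0)
  expect_error(genotypic_value(c(S1_1 = "QQ"), arch), "misses loci")
})

test_that("additive-only sets are antisymmetric in QQ vs qq", {
  arch <- toy_arch(sprintf("S1_%d", 1:5), a = c(2, -1, 0.5, 3, -0.25), d = 0)
  loci <- arch$loci$snp
  vQQ <- genotypic_value(setNames(rep("QQ", 5), loci), arch)
  vqq <- genotypic_value(setNames(rep("qq", 5), loci), arch)
  expect_equal(vqq, -vQQ)
})

test_that("enumeration solves the trivial one-locus cases", {
  arch <- toy_arch("S1_1", a = 2, d = 0)
  e <- enumerate_optimum(arch, c("QQ", "qq"))
  expect_equal(unname(e$genotype), "QQ")
  expect_equal(e$value, 2)

  arch2 <- toy_arch("S1_1", a = 1, d = 3)
  e2 <- enumerate_optimum(arch2, c("QQ", "Qq", "qq"))
  expect_equal(unname(e2$genotype), "Qq")  # d > a forces the heterozygote
  expect_equal(e2$value, 3)
})

test_that("enumeration matches an independent brute force with epistasis", {
  arch <- random_effect_set(6, 3, seed = 11)
  for (allowed in list(c("QQ", "qq"), c("QQ", "Qq", "qq"))) {
    e <- enumerate_optimum(arch, allowed)
    bf <- brute_force_optimum(arch, allowed)
    expect_equal(e$value, bf$value)
    expect_equal(genotypic_value(e$genotype, arch), e$value)
  }
})

test_that("enumeration refuses oversized searches, directing to tuning", {
  arch <- random_effect_set(16, 2, seed = 12)
  expect_error(enumerate_optimum(arch, c("QQ", "qq")), "stepwise_tune")
})

test_that("stepwise tuning solves separable objectives in one sweep", {
  arch <- toy_arch(sprintf("S1_%d", 1:6),
                   a = c(1, -2, 0.5, 3, -0.1, 0.7), d = 0)
  s <- stepwise_tune(arch, c("QQ", "qq"))
  e <- enumerate_optimum(arch, c("QQ", "qq"))
  expect_equal(s$value, e$value)
  expect_equal(s$sweeps, 1L)
})

test_that("stepwise tuning is a fixed point at the optimum and monotone", {
  arch <- random_effect_set(7, 4, seed = 13)
  e <- enumerate_optimum(arch, c("QQ", "Qq", "qq"), max_loci = 7)
  s <- stepwise_tune(arch, c("QQ", "Qq", "qq"), start_vector = e$genotype)
  expect_identical(s$genotype, e$genotype)
  expect_equal(s$value, e$value)
})

test_that("stepwise tuning nearly always attains the enumeration optimum", {
  matches <- 0L
  for (seed in 1:40) {
    arch <- random_effect_set(6, 2, seed = 3000 + seed)
    e <- enumerate_optimum(arch, c("QQ", "Qq", "qq"), max_loci = 6)
    s <- stepwise_tune(arch, c("QQ", "Qq", "qq"))
    expect_lte(s$value, e$value + 1e-9)  # never exceeds the exact optimum
    matches <- matches + (abs(s$value - e$value) < 1e-9)
  }
  expect_gte(matches, 38L)
})

test_that("best existing line is found, with per-environment switches", {
  g <- simulate_nam_genotypes(2, 40, 4, het_rate = 0, missing_rate = 0,
                              seed = 14)
  arch <- toy_arch(g$snps$snp[1:2], a = c(1, 0.5), env_effects = c(0, 0),
                   ae = rbind(c(3, -3), c(0, 0)), residual_sd = 1)
  bl <- best_existing_line(g, arch)
  vals <- vapply(g$lines, function(l) {
    genotypic_value(setNames(g$codes[l, arch$loci$snp], arch$loci$snp), arch)
  }, 0)
  expect_equal(bl$value[bl$scope == "overall"], max(vals))
  expect_equal(bl$line[bl$scope == "overall"],
               sort(names(vals)[vals == max(vals)])[1])
  # the sign-flipping ae on locus 1 makes different lines win per env
  ev1 <- bl[bl$scope == "env1", ]
  ev2 <- bl[bl$scope == "env2", ]
  g1 <- g$codes[ev1$line, g$snps$snp[1]]
  g2 <- g$codes[ev2$line, g$snps$snp[1]]
  expect_false(identical(g1, g2))
})

test_that("a planted optimum line is recovered as best", {
  g <- simulate_nam_genotypes(2, 30, 5, het_rate = 0.2, missing_rate = 0,
                              seed = 15)
  arch <- toy_arch(g$snps$snp, a = c(2, 1, -1, 0.5, -0.5), d = 0)
  codes <- g$codes
  codes[1, ] <- c("QQ", "QQ", "qq", "QQ", "qq")  # the exact optimum
  g2 <- geno_matrix(codes, g$families)
  bl <- best_existing_line(g2, arch)
  expect_equal(bl$line[bl$scope == "overall"], g2$lines[1])
  expect_equal(bl$value[bl$scope == "overall"], sum(abs(arch$loci$a)))
})

test_that("breeding table honors the search-space nesting", {
  for (seed in c(21, 22, 23)) {
    arch <- random_effect_set(5, 2, seed = seed)
    arch$env_effects <- c(0.5, -0.5)
    g <- simulate_nam_genotypes(3, 50, 5, het_rate = 0, missing_rate = 0,
                                seed = seed + 100)
    colnames(g$codes) <- arch$loci$snp
    g$snps <- parse_snp_id(arch$loci$snp)
    bp <- predict_breeding_table(arch, g)
    for (s in names(bp)[-1]) {
      expect_gte(bp[[s]][6], bp[[s]][5])  # superior line >= best line
      expect_gte(bp[[s]][7], bp[[s]][6])  # superior hybrid >= superior line
    }
    sl <- attr(bp, "superior_line_genotypes")
    expect_false(any(unlist(sl) == "Qq"))
  }
})

test_that("a single additive locus makes line and hybrid coincide", {
  g <- simulate_nam_genotypes(2, 20, 1, het_rate = 0, seed = 24)
  arch <- toy_arch(g$snps$snp, a = 1.5, d = 0)
  bp <- predict_breeding_table(arch, g)
  expect_equal(bp$G[6], bp$G[7])
})

test_that("large dd effects push the hybrid strictly above the line", {
  g <- simulate_nam_genotypes(2, 20, 2, het_rate = 0.3, seed = 25)
  arch <- genetic_architecture(
    loci = data.frame(snp = g$snps$snp, a = c(0.2, 0.1), d = c(0, 0)),
    pairs = data.frame(snp1 = g$snps$snp[1], snp2 = g$snps$snp[2],
                       aa = 0, ad = 0, da = 0, dd = 5))
  bp <- predict_breeding_table(arch, g)
  expect_gt(bp$G[7], bp$G[6])
  sh <- attr(bp, "superior_hybrid_genotypes")$G
  expect_equal(unname(sh), c("Qq", "Qq"))
})

test_that("without interactions the per-environment columns all agree", {
  g <- simulate_nam_genotypes(2, 20, 3, het_rate = 0.1, seed = 26)
  arch <- toy_arch(g$snps$snp, a = c(1, -0.5, 0.25), d = c(0.3, 0, 0),
                   env_effects = c(0, 0))
  bp <- predict_breeding_table(arch, g)
  for (row in c(2:4, 5:7)) {
    expect_equal(bp$G_GE1[row], bp$G[row])
    expect_equal(bp$G_GE2[row], bp$G[row])
  }
})
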