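test_that("a pure-noise locus scores near one half", {
  g <- simulate_nam_genotypes(10, 200, 1, het_rate = 0.05, missing_rate = 0,
                              seed = 41)
  ph <- toy_pheno(g$lines, withr::with_seed(42, rnorm(2000)))
  res <- gmdr_residuals(ph)
  sc <- gmdr_score(res, g, g$snps$snp[1], seed = 1)
  expect_lt(abs(sc - 0.5), 0.03)
})

test_that("a fully determining locus scores 1", {
  codes <- matrix(rep(c("QQ", "qq"), each = 50), ncol = 1,
                  dimnames = list(sprintf("L%03d", 1:100), "S1_100"))
  g <- toy_geno(codes)
  ph <- toy_pheno(g$lines, ifelse(codes[, 1] == "QQ", 2, -2))
  sc <- gmdr_score(gmdr_residuals(ph), g, "S1_100", seed = 1)
  expect_equal(sc, 1)
})

test_that("a dd-only pair outscores its constituent loci in 2D", {
  g <- simulate_nam_genotypes(5, 300, 2, het_rate = 0.4, missing_rate = 0,
                              seed = 43)
  arch <- genetic_architecture(
    loci = data.frame(snp = g$snps$snp, a = 0, d = 0),
    pairs = data.frame(snp1 = g$snps$snp[1], snp2 = g$snps$snp[2],
                       aa = 0, ad = 0, da = 0, dd = 4),
    residual_sd = 0.5)
  ph <- simulate_phenotypes(g, arch, n_envs = 1, seed = 44)
  res <- gmdr_residuals(ph)
  s1 <- gmdr_score(res, g, g$snps$snp[1], seed = 2)
  s2 <- gmdr_score(res, g, g$snps$snp[2], seed = 2)
  s12 <- gmdr_score(res, g, g$snps$snp, seed = 2)
  expect_gt(s12, s1)
  expect_gt(s12, s2)
})

test_that("the score is invariant to affine phenotype transformations", {
  g <- simulate_nam_genotypes(4, 100, 3, het_rate = 0.1, missing_rate = 0,
                              seed = 45)
  arch <- toy_arch(g$snps$snp[1], a = 0.8)
  ph <- simulate_phenotypes(g, arch, n_envs = 2, seed = 46)
  ph2 <- ph
  ph2$value <- 3.7 * ph2$value + 11
  for (s in g$snps$snp) {
    expect_equal(gmdr_score(gmdr_residuals(ph), g, s, seed = 5),
                 gmdr_score(gmdr_residuals(ph2), g, s, seed = 5))
  }
})

test_that("the scan ranks a causal SNP first in nearly all replicates", {
  hits <- 0L
  for (rep in 1:20) {
    g <- simulate_nam_genotypes(10, 200, 101, het_rate = 0.03,
                                missing_rate = 0, seed = 400 + rep)
    causal <- g$snps$snp[51]
    arch <- toy_arch(causal, a = 1, residual_sd = 1.5)  # h2 around 0.1
    ph <- simulate_phenotypes(g, arch, n_envs = 1, seed = 500 + rep)
    cs <- gmdr_scan(ph, g, dims = 1L, top_k = 5L, seed = 600 + rep)
    hits <- hits + (cs$loci$snp[1] == causal)
  }
  expect_gte(hits, 19L)
})

test_that("scan edge cases: top_k overflow, 1D-only dims, bad dims", {
  g <- simulate_nam_genotypes(2, 50, 5, het_rate = 0.05, seed = 47)
  ph <- toy_pheno(g$lines, withr::with_seed(48, rnorm(100)))
  cs <- gmdr_scan(ph, g, dims = 1L, top_k = 100L, seed = 1)
  expect_equal(nrow(cs$loci), 5L)
  expect_equal(nrow(cs$pairs), 0L)
  expect_error(gmdr_scan(ph, g, dims = 4L), "subset")
  expect_error(gmdr_score(gmdr_residuals(ph), g, g$snps$snp[1:4]),
               "tuple size")
})

test_that("the null maximum 1D score shrinks with sample size", {
  max_score <- function(n, seed) {
    g <- simulate_nam_genotypes(5, n / 5, 20, het_rate = 0.03,
                                missing_rate = 0, seed = seed)
    ph <- toy_pheno(g$lines, withr::with_seed(seed + 1, rnorm(n)))
    cs <- gmdr_scan(ph, g, dims = 1L, top_k = 1L, seed = seed + 2)
    cs$loci$score[1]
  }
  small <- mean(vapply(1:3, function(i) max_score(500, 700 + 10 * i), 0))
  large <- mean(vapply(1:3, function(i) max_score(8000, 800 + 10 * i), 0))
  expect_gt(small, large)
})

test_that("candidate sets rank deterministically and expand into terms", {
  g <- simulate_nam_genotypes(4, 100, 10, het_rate = 0.2, seed = 49)
  arch <- genetic_architecture(
    loci = data.frame(snp = g$snps$snp[1:2], a = c(1, 0.5), d = 0),
    pairs = data.frame(snp1 = g$snps$snp[1], snp2 = g$snps$snp[2],
                       aa = 1, ad = 0, da = 0, dd = 0),
    residual_sd = 1)
  ph <- simulate_phenotypes(g, arch, n_envs = 1, seed = 50)
  cs1 <- gmdr_scan(ph, g, dims = c(1L, 2L), top_k = 4L, survivors = 5L,
                   seed = 3)
  cs2 <- gmdr_scan(ph, g, dims = c(1L, 2L), top_k = 4L, survivors = 5L,
                   seed = 3)
  expect_identical(cs1$loci, cs2$loci)
  expect_identical(cs1$pairs, cs2$pairs)
  expect_true(all(diff(cs1$loci$score) <= 0))
  expect_true(all(cs1$loci$score >= 0 & cs1$loci$score <= 1))

  terms <- candidate_terms(cs1)
  expect_true(all(c(cs1$pairs$snp1, cs1$pairs$snp2) %in% terms$loci))
  expect_false(any(duplicated(paste(terms$pairs$snp1, terms$pairs$snp2))))
})
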