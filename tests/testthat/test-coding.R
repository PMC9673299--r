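test_that("single-locus coefficients follow the model's coding", {
  expect_equal(encode_locus("QQ"), data.frame(x_A = 1, x_D = 0))
  expect_equal(encode_locus("Qq"), data.frame(x_A = 0, x_D = 1))
  expect_equal(encode_locus("qq"), data.frame(x_A = -1, x_D = 0))
  expect_error(encode_locus("QX"), "invalid genotype code")
})

test_that("epistasis coefficients match the definitions on all 9 pairs", {
  combos <- expand.grid(i = c("QQ", "Qq", "qq"), j = c("QQ", "Qq", "qq"),
                        stringsAsFactors = FALSE)
  got <- encode_epistasis(combos$i, combos$j)
  # expected table transcribed from the coefficient definitions:
  # x_AA: 1 for QQxQQ and qqxqq, -1 for QQxqq and qqxQQ, 0 otherwise
  # x_AD: 1 for QQxQq, -1 for qqxQq;  x_DA: 1 for QqxQQ, -1 for Qqxqq
  # x_DD: 1 for QqxQq
  key <- paste(combos$i, combos$j, sep = "x")
  expected <- data.frame(
    x_AA = c(1, 0, -1, 0, 0, 0, -1, 0, 1),
    x_AD = c(0, 0, 0, 1, 0, -1, 0, 0, 0),
    x_DA = c(0, 1, 0, 0, 0, 0, 0, -1, 0),
    x_DD = c(0, 0, 0, 0, 1, 0, 0, 0, 0),
    row.names = NULL
  )
  # combos rows: QQxQQ QqxQQ qqxQQ QQxQq QqxQq qqxQq QQxqq Qqxqq qqxqq
  expect_equal(got, expected, ignore_attr = TRUE)
  # and the named examples
  expect_equal(unlist(encode_epistasis("QQ", "qq")),
               c(x_AA = -1, x_AD = 0, x_DA = 0, x_DD = 0))
  expect_equal(unlist(encode_epistasis("Qq", "Qq")),
               c(x_AA = 0, x_AD = 0, x_DA = 0, x_DD = 1))
  expect_equal(unlist(encode_epistasis("qq", "Qq")),
               c(x_AA = 0, x_AD = -1, x_DA = 0, x_DD = 0))
})

test_that("epistasis coefficients equal products of main-effect contrasts", {
  combos <- expand.grid(i = c("QQ", "Qq", "qq"), j = c("QQ", "Qq", "qq"),
                        stringsAsFactors = FALSE)
  ci <- encode_locus(combos$i); cj <- encode_locus(combos$j)
  ep <- encode_epistasis(combos$i, combos$j)
  expect_equal(ep$x_AA, ci$x_A * cj$x_A)
  expect_equal(ep$x_AD, ci$x_A * cj$x_D)
  expect_equal(ep$x_DA, ci$x_D * cj$x_A)
  expect_equal(ep$x_DD, ci$x_D * cj$x_D)
})

test_that("missing codes are imputed with the family-mean coefficient", {
  codes <- rbind(c("QQ"), c("QQ"), c("qq"), c(NA))
  colnames(codes) <- "S1_100"
  rownames(codes) <- sprintf("L%d", 1:4)
  g <- geno_matrix(codes, rep("F01", 4))
  xA <- locus_coefficients(g)$xA
  expect_equal(unname(xA[4, 1]), mean(c(1, 1, -1)))
})

test_that("design matrices have the contracted shapes and values", {
  codes <- rbind(c("QQ"), c("qq"))
  colnames(codes) <- "S1_100"
  rownames(codes) <- c("L1", "L2")
  g <- geno_matrix(codes, c("F01", "F01"))
  ph <- pheno_table(rep(c("L1", "L2"), 2), "F01", rep(1:2, each = 2),
                    "trait", rnorm(4))
  dm <- build_design(g, ph, loci = "S1_100")
  expect_equal(dim(dm$X), c(4L, 2L))          # a and d columns
  expect_equal(dim(dm$Z$AE), c(4L, 2L))       # locus x 2 environments
  expect_equal(dim(dm$Z$env), c(4L, 2L))
  expect_equal(unname(dm$X[, "a@S1_100"]), c(1, -1, 1, -1))
  expect_equal(unname(dm$X[, "d@S1_100"]), rep(0, 4))
})

test_that("u-blocks are fixed coefficients masked by environment", {
  g <- simulate_nam_genotypes(2, 25, 6, het_rate = 0.2, missing_rate = 0,
                              seed = 21)
  arch <- toy_arch(g$snps$snp[1:3], a = c(1, 0, -1), env_effects = c(1, -1))
  ph <- simulate_phenotypes(g, arch, n_envs = 2, seed = 22)
  dm <- build_design(g, ph, arch$loci$snp)
  for (h in 1:2) {
    for (s in arch$loci$snp) {
      expect_equal(
        unname(dm$Z$AE[, paste0("ae@", s, ":env", h)]),
        unname(dm$X[, paste0("a@", s)]) * (ph$env == h))
      expect_equal(
        unname(dm$Z$DE[, paste0("de@", s, ":env", h)]),
        unname(dm$X[, paste0("d@", s)]) * (ph$env == h))
    }
  }
})

test_that("family means of x_A equal freq(QQ) - freq(qq)", {
  g <- simulate_nam_genotypes(4, 80, 10, het_rate = 0.1, missing_rate = 0,
                              seed = 23)
  xA <- locus_coefficients(g)$xA
  for (f in unique(g$families)) {
    rows <- g$families == f
    expect_equal(
      colMeans(xA[rows, , drop = FALSE]),
      colMeans(g$codes[rows, , drop = FALSE] == "QQ") -
        colMeans(g$codes[rows, , drop = FALSE] == "qq"))
  }
})

test_that("principal components separate divergent families", {
  set.seed(31)
  n_snps <- 60
  f1 <- matrix(ifelse(runif(40 * n_snps) < 0.9, "QQ", "qq"), 40, n_snps)
  f2 <- matrix(ifelse(runif(40 * n_snps) < 0.1, "QQ", "qq"), 40, n_snps)
  codes <- rbind(f1, f2)
  colnames(codes) <- sprintf("S1_%d", seq_len(n_snps) * 100L)
  rownames(codes) <- sprintf("L%03d", 1:80)
  g <- geno_matrix(codes, rep(c("F01", "F02"), each = 40))
  pcs <- compute_pcs(g, 2)
  r <- cor(pcs[, 1], as.numeric(factor(g$families)))
  expect_gt(abs(r), 0.9)
})

test_that("PC edge cases: k = 0 block, duplicated lines, k too large", {
  g <- simulate_nam_genotypes(2, 10, 8, seed = 25)
  expect_equal(ncol(compute_pcs(g, 0)), 0L)
  expect_error(compute_pcs(g, 50), "smaller than")

  codes <- g$codes
  codes[2, ] <- codes[1, ]
  g2 <- geno_matrix(codes, g$families)
  pcs <- compute_pcs(g2, 2)
  expect_equal(unname(pcs[1, ]), unname(pcs[2, ]))
})

test_that("the base model is the PC-adjusted design with an empty cofactor block", {
  g <- simulate_nam_genotypes(2, 20, 6, seed = 26)
  arch <- toy_arch(g$snps$snp[1], a = 1)
  ph <- simulate_phenotypes(g, arch, n_envs = 2, seed = 27)
  dm0 <- build_design(g, ph, arch$loci$snp, n_pcs = 0)
  dm2 <- build_design(g, ph, arch$loci$snp, n_pcs = 2)
  expect_identical(dm0$X, dm2$X)
  expect_identical(dm0$Z, dm2$Z)
  expect_equal(ncol(dm0$C), 0L)
  expect_equal(ncol(dm2$C), 2L)
})

test_that("build_design reports unknown phenotype lines", {
  g <- simulate_nam_genotypes(1, 5, 3, seed = 28)
  ph <- toy_pheno(c(g$lines[1], "GHOST"), c(1, 2))
  expect_error(build_design(g, ph, g$snps$snp[1]), "GHOST")
})

test_that("design matrices export to TSV with one row per record", {
  g <- simulate_nam_genotypes(2, 10, 3, het_rate = 0.1, seed = 30)
  arch <- toy_arch(g$snps$snp[1], a = 1)
  ph <- simulate_phenotypes(g, arch, n_envs = 2, seed = 31)
  dm <- build_design(g, ph, g$snps$snp[1])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_design_matrices(dm, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), nrow(ph))
  expect_true("a.S1_100000" %in% names(tab) || "a@S1_100000" %in% names(tab))
})
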