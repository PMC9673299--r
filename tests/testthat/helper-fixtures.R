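# small programmatic fixtures shared across test files

# genotype matrix from an explicit code matrix (one family unless given)
toy_geno <- function(codes, families = NULL) {
  if (is.null(rownames(codes))) {
    rownames(codes) <- sprintf("Z01E%04d", seq_len(nrow(codes)))
  }
  if (is.null(colnames(codes))) {
    colnames(codes) <- sprintf("S1_%d", seq_len(ncol(codes)) * 1000L)
  }
  if (is.null(families)) families <- rep("F01", nrow(codes))
  geno_matrix(codes, families)
}

# single-trait single-env phenotype table for given lines/values
toy_pheno <- function(lines, values, env = 1L, family = "F01",
                      trait = "trait") {
  pheno_table(lines, rep(family, length(lines)), rep(env, length(lines)),
              trait, values)
}

# balanced one-locus fixture: n lines per genotype class
balanced_locus_geno <- function(n_per_class = 10L) {
  codes <- matrix(rep(c("QQ", "Qq", "qq"), each = n_per_class), ncol = 1,
                  dimnames = list(sprintf("Z01E%04d", seq_len(3 * n_per_class)),
                                  "S1_1000"))
  toy_geno(codes)
}

# architecture with given per-locus effects over existing snp ids
toy_arch <- function(snps, a, d = 0, pairs = NULL, env_effects = NULL,
                     ae = NULL, de = NULL, mu = 0, residual_sd = 1, ...) {
  genetic_architecture(
    mu = mu, loci = data.frame(snp = snps, a = a, d = d),
    pairs = pairs, env_effects = env_effects, ae = ae, de = de,
    residual_sd = residual_sd, ...)
}

# random epistatic effect set for breeding-search oracles
random_effect_set <- function(n_loci, n_pairs, seed) {
  withr::with_seed(seed, {
    snps <- sprintf("S1_%d", seq_len(n_loci) * 1000L)
    cmb <- utils::combn(snps, 2L)
    sel <- sample(ncol(cmb), n_pairs)
    genetic_architecture(
      loci = data.frame(snp = snps, a = rnorm(n_loci), d = rnorm(n_loci)),
      pairs = data.frame(snp1 = cmb[1, sel], snp2 = cmb[2, sel],
                         aa = rnorm(n_pairs), ad = rnorm(n_pairs),
                         da = rnorm(n_pairs), dd = rnorm(n_pairs)),
      residual_sd = 1)
  })
}

# brute-force optimum by explicit expansion (independent of the package's
# chunked enumeration)
brute_force_optimum <- function(arch, allowed, env = NULL) {
  loci <- arch$loci$snp
  grid <- expand.grid(rep(list(allowed), length(loci)),
                      stringsAsFactors = FALSE)
  vals <- apply(grid, 1L, function(g)
    genotypic_value(setNames(as.character(g), loci), arch, env))
  list(value = max(vals),
       genotype = setNames(as.character(grid[which.max(vals), ]), loci))
}
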