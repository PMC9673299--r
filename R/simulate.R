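#' Simulate NAM-like genotypes
#'
#' Generates a nested-association-mapping style population: half-sib
#' families of recombinant inbred lines (RILs) sharing the common parent
#' B73.  At each SNP a family segregates only if its non-B73 founder
#' carries the alternative (Q) allele, which happens with probability
#' \code{seg_prob} independently per family and SNP.  In a segregating
#' family each RIL is QQ or qq with probability 1/2 (the expected B73
#' allele frequency among homozygotes is 0.5); in a non-segregating family
#' all lines are qq (the B73 homozygote).  Residual heterozygosity after
#' selfing is emulated by overwriting each cell with Qq independently with
#' probability \code{het_rate}, and missing calls by overwriting with NA at
#' rate \code{missing_rate}.
#'
#' Genotypes are drawn i.i.d. across SNPs within a family; no linkage map
#' is simulated.
#'
#' @param n_families number of RIL families.
#' @param lines_per_family number of lines per family.
#' @param n_snps number of SNPs.
#' @param het_rate per-cell residual heterozygosity rate in [0, 1).
#' @param missing_rate per-cell missing-call rate in [0, 1).
#' @param seed integer seed; identical calls with the same seed return
#'   byte-identical matrices.
#' @param seg_prob probability that a family segregates at a SNP.
#' @param chrom_count SNP ids are assigned round-robin to this many
#'   chromosomes with increasing positions.
#' @return a [geno_matrix()].  Line ids are \code{Z<fam>E<line>}, family
#'   labels \code{F01..}; SNP ids \code{S<chrom>_<pos>}.
#' @examples
#' g <- simulate_nam_genotypes(2, 10, 5, het_rate = 0, missing_rate = 0, seed = 1)
#' table(g$codes)
#' @export
simulate_nam_genotypes <- function(n_families, lines_per_family, n_snps,
                                   het_rate = 0.03, missing_rate = 0,
                                   seed = 1L, seg_prob = 0.5,
                                   chrom_count = 10L) {
  n_families <- .check_count(n_families, "n_families")
  lines_per_family <- .check_count(lines_per_family, "lines_per_family")
  n_snps <- .check_count(n_snps, "n_snps")
  het_rate <- .check_fraction(het_rate, "het_rate")
  missing_rate <- .check_fraction(missing_rate, "missing_rate")
  n_lines <- n_families * lines_per_family

  chrom <- rep_len(seq_len(chrom_count), n_snps)
  pos <- integer(n_snps)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    pos[sel] <- seq_len(sum(sel)) * 100000L
  }
  snp_ids <- sprintf("S%d_%d", chrom, pos)
  fam_labels <- sprintf("F%02d", seq_len(n_families))
  line_fam <- rep(fam_labels, each = lines_per_family)
  line_ids <- sprintf("Z%02dE%04d", rep(seq_len(n_families), each = lines_per_family),
                      rep(seq_len(lines_per_family), n_families))

  codes <- withr::with_seed(seed, {
    m <- matrix("qq", n_lines, n_snps, dimnames = list(line_ids, snp_ids))
    seg <- matrix(runif(n_families * n_snps) < seg_prob, n_families, n_snps)
    for (f in seq_len(n_families)) {
      rows <- which(line_fam == fam_labels[f])
      segg <- which(seg[f, ])
      if (length(segg) > 0L) {
        draws <- matrix(
          ifelse(runif(length(rows) * length(segg)) < 0.5, "QQ", "qq"),
          length(rows), length(segg))
        m[rows, segg] <- draws
      }
    }
    if (het_rate > 0) {
      het <- matrix(runif(n_lines * n_snps) < het_rate, n_lines, n_snps)
      m[het] <- "Qq"
    }
    if (missing_rate > 0) {
      mis <- matrix(runif(n_lines * n_snps) < missing_rate, n_lines, n_snps)
      m[mis] <- NA_character_
    }
    m
  })
  geno_matrix(codes, line_fam)
}

#' Simulate multi-environment phenotypes under the full genetic model
#'
#' Evaluates the full genetic model at every (line, environment) cell:
#' mean + additive + dominance + digenic epistasis + environment effect +
#' gene-by-environment interaction deviations + Gaussian residual with the
#' architecture's residual standard deviation.  Coefficients follow the
#' standard coding (see [encode_locus()], [encode_epistasis()]).
#'
#' @param geno a [geno_matrix()]; must contain every SNP the architecture
#'   references.
#' @param arch a [genetic_architecture()].
#' @param n_envs number of environments; must match the architecture's
#'   environment dimension when that is set.
#' @param seed integer seed for the residual draws.
#' @param trait trait name recorded in the output table.
#' @return a [pheno_table()] with one record per line x environment.
#' @export
simulate_phenotypes <- function(geno, arch, n_envs = n_envs_of(arch),
                                seed = 1L, trait = "trait") {
  stopifnot(inherits(geno, "geno_matrix"), inherits(arch, "genetic_architecture"))
  n_envs <- .check_count(n_envs, "n_envs")
  if (!is.null(arch$env_effects) && length(arch$env_effects) != n_envs) {
    stop("`n_envs` conflicts with the architecture's environment effects",
         call. = FALSE)
  }
  unknown <- setdiff(arch$loci$snp, geno$snps$snp)
  if (length(unknown) > 0L) {
    stop("architecture references SNP(s) absent from genotypes: ",
         paste(head(unknown, 5L), collapse = ", "), call. = FALSE)
  }

  g_main <- genotypic_value_lines(geno, arch, env = NULL)
  n_lines <- length(g_main)
  env_eff <- if (is.null(arch$env_effects)) rep(0, n_envs) else arch$env_effects

  values <- matrix(0, n_lines, n_envs)
  for (h in seq_len(n_envs)) {
    gxe_h <- genotypic_value_lines(geno, arch, env = h, gxe_only = TRUE)
    values[, h] <- arch$mu + g_main + env_eff[h] + gxe_h
  }
  eps <- withr::with_seed(seed,
    matrix(rnorm(n_lines * n_envs, 0, arch$residual_sd), n_lines, n_envs))
  values <- values + eps

  pheno_table(
    line = rep(geno$lines, n_envs),
    family = rep(unname(geno$families), n_envs),
    env = rep(seq_len(n_envs), each = n_lines),
    trait = trait,
    value = as.vector(values)
  )
}

#' @keywords internal
#' Per-line genetic value under an architecture (vectorized over lines).
#' env = NULL gives main effects only; gxe_only = TRUE gives only the
#' environment-specific deviations of environment `env`.
genotypic_value_lines <- function(geno, arch, env = NULL, gxe_only = FALSE) {
  loci <- arch$loci$snp
  coefs <- locus_coefficients(geno, union(loci, c(arch$pairs$snp1, arch$pairs$snp2)))
  xA <- coefs$xA[, loci, drop = FALSE]
  xD <- coefs$xD[, loci, drop = FALSE]
  pc <- if (nrow(arch$pairs) > 0L) pair_coefficients(coefs, arch$pairs) else NULL

  main <- function(a, d, aa, ad, da, dd) {
    v <- drop(xA %*% a) + drop(xD %*% d)
    if (!is.null(pc)) {
      v <- v + drop(pc$xAA %*% aa) + drop(pc$xAD %*% ad) +
        drop(pc$xDA %*% da) + drop(pc$xDD %*% dd)
    }
    v
  }
  if (is.null(env)) {
    return(main(arch$loci$a, arch$loci$d,
                arch$pairs$aa, arch$pairs$ad, arch$pairs$da, arch$pairs$dd))
  }
  pick <- function(m, nr) if (is.null(m)) rep(0, nr) else m[, env]
  v <- main(pick(arch$ae, nrow(arch$loci)), pick(arch$de, nrow(arch$loci)),
            pick(arch$aae, nrow(arch$pairs)), pick(arch$ade, nrow(arch$pairs)),
            pick(arch$dae, nrow(arch$pairs)), pick(arch$dde, nrow(arch$pairs)))
  if (gxe_only) v else v + main(arch$loci$a, arch$loci$d, arch$pairs$aa,
                                arch$pairs$ad, arch$pairs$da, arch$pairs$dd)
}

#' Construct an architecture with target component heritabilities
#'
#' Draws raw effects for the requested components and rescales them so
#' that, on a reference NAM population generated with the same seed, the
#' realized variance share of each component matches its target.  The
#' residual standard deviation is fixed at 1 and the total phenotypic
#' variance solves \code{V_P = (v_env + 1) / (1 - sum(targets))}, where
#' v_env is the realized variance of the environment main effects; each
#' component's effects are scaled so its realized contribution variance is
#' \code{target * V_P}.
#'
#' @param n_loci number of loci with main effects.
#' @param n_pairs number of epistatic pairs (formed from the first loci).
#' @param target_h2 named numeric vector of target variance shares; valid
#'   names are \code{A, D, AA, AD, DA, DD, AE, DE, AAE, ADE, DAE, DDE}.
#'   All values >= 0 with sum < 1.
#' @param seed integer seed (draws effects and the reference population).
#' @param n_envs number of environments (needed for any *E component).
#' @param env_sd standard deviation of the environment main effects e_h.
#' @param ref_geno optional [geno_matrix()] to use as the reference
#'   population; default simulates 25 families x 200 lines over the
#'   required loci.
#' @param mu population mean of the architecture.
#' @return a [genetic_architecture()] whose realized component
#'   heritabilities on the reference population approximate
#'   \code{target_h2}.
#' @export
make_architecture <- function(n_loci, n_pairs = 0, target_h2, seed = 1L,
                              n_envs = 4L, env_sd = 1, ref_geno = NULL,
                              mu = 0) {
  n_loci <- .check_count(n_loci, "n_loci")
  n_pairs <- .check_count(n_pairs, "n_pairs", min = 0L)
  valid <- c("A", "D", "AA", "AD", "DA", "DD",
             "AE", "DE", "AAE", "ADE", "DAE", "DDE")
  if (length(target_h2) > 0L) {
    if (is.null(names(target_h2)) || !all(names(target_h2) %in% valid)) {
      stop("`target_h2` must be named with components among: ",
           paste(valid, collapse = ", "), call. = FALSE)
    }
    if (any(target_h2 < 0)) stop("`target_h2` fractions must be >= 0", call. = FALSE)
    if (sum(target_h2) >= 1) {
      stop("`target_h2` components must sum to < 1", call. = FALSE)
    }
  }
  targets <- setNames(rep(0, length(valid)), valid)
  targets[names(target_h2)] <- target_h2
  pair_components <- c("AA", "AD", "DA", "DD", "AAE", "ADE", "DAE", "DDE")
  if (n_pairs == 0L && any(targets[pair_components] > 0)) {
    stop("pair components targeted but `n_pairs` is 0", call. = FALSE)
  }

  if (is.null(ref_geno)) {
    ref_geno <- simulate_nam_genotypes(
      25L, 200L, max(n_loci, 2L), het_rate = 0.2, missing_rate = 0,
      seed = split_seed(seed, 11L))
  }
  loci_ids <- ref_geno$snps$snp[seq_len(n_loci)]
  pairs <- if (n_pairs > 0L) {
    cmb <- utils::combn(loci_ids, 2L)
    if (n_pairs > ncol(cmb)) stop("`n_pairs` exceeds available locus pairs", call. = FALSE)
    data.frame(snp1 = cmb[1L, seq_len(n_pairs)], snp2 = cmb[2L, seq_len(n_pairs)],
               aa = 0, ad = 0, da = 0, dd = 0, stringsAsFactors = FALSE)
  } else NULL

  coefs <- locus_coefficients(ref_geno, loci_ids)
  pcf <- if (n_pairs > 0L) pair_coefficients(coefs, pairs) else NULL
  env_eff <- withr::with_seed(split_seed(seed, 12L), rnorm(n_envs, 0, env_sd))
  env_eff <- env_eff - mean(env_eff)
  v_env <- mean(env_eff^2)  # variance over records, envs equally replicated

  V_P <- (v_env + 1) / (1 - sum(targets))

  draw <- withr::with_seed(split_seed(seed, 13L), {
    list(
      a = rnorm(n_loci), d = rnorm(n_loci),
      aa = rnorm(max(n_pairs, 1L)), ad = rnorm(max(n_pairs, 1L)),
      da = rnorm(max(n_pairs, 1L)), dd = rnorm(max(n_pairs, 1L)),
      ae = matrix(rnorm(n_loci * n_envs), n_loci, n_envs),
      de = matrix(rnorm(n_loci * n_envs), n_loci, n_envs),
      aae = matrix(rnorm(max(n_pairs, 1L) * n_envs), max(n_pairs, 1L), n_envs),
      ade = matrix(rnorm(max(n_pairs, 1L) * n_envs), max(n_pairs, 1L), n_envs),
      dae = matrix(rnorm(max(n_pairs, 1L) * n_envs), max(n_pairs, 1L), n_envs),
      dde = matrix(rnorm(max(n_pairs, 1L) * n_envs), max(n_pairs, 1L), n_envs)
    )
  })

  # realized variance of a main component with raw effects b over columns M
  scale_main <- function(b, M, target) {
    if (target == 0) return(b * 0)
    contrib <- drop(M %*% b)
    v <- mean((contrib - mean(contrib))^2)
    if (v <= 0) stop("component has no realized variance on the reference population",
                     call. = FALSE)
    b * sqrt(target * V_P / v)
  }
  # interaction deviations: center per row across envs so they are pure
  # deviations, then scale to target share over records (equal env weights)
  scale_gxe <- function(B, M, target) {
    B <- B - rowMeans(B)
    if (target == 0) return(B * 0)
    contrib <- M %*% B  # lines x envs
    v <- mean((contrib - mean(contrib))^2)
    if (v <= 0) stop("interaction component has no realized variance", call. = FALSE)
    B * sqrt(target * V_P / v)
  }

  xAA <- if (n_pairs > 0L) pcf$xAA else NULL
  xAD <- if (n_pairs > 0L) pcf$xAD else NULL
  xDA <- if (n_pairs > 0L) pcf$xDA else NULL
  xDD <- if (n_pairs > 0L) pcf$xDD else NULL

  loci_df <- data.frame(
    snp = loci_ids,
    a = scale_main(draw$a, coefs$xA, targets["A"]),
    d = scale_main(draw$d, coefs$xD, targets["D"]),
    stringsAsFactors = FALSE
  )
  if (n_pairs > 0L) {
    pairs$aa <- scale_main(draw$aa[seq_len(n_pairs)], xAA, targets["AA"])
    pairs$ad <- scale_main(draw$ad[seq_len(n_pairs)], xAD, targets["AD"])
    pairs$da <- scale_main(draw$da[seq_len(n_pairs)], xDA, targets["DA"])
    pairs$dd <- scale_main(draw$dd[seq_len(n_pairs)], xDD, targets["DD"])
  }

  mk <- function(B, M, target, nr) {
    if (target == 0) return(NULL)
    scale_gxe(B[seq_len(nr), , drop = FALSE], M, target)
  }
  arch <- genetic_architecture(
    mu = mu, loci = loci_df, pairs = pairs, env_effects = env_eff,
    ae = mk(draw$ae, coefs$xA, targets["AE"], n_loci),
    de = mk(draw$de, coefs$xD, targets["DE"], n_loci),
    aae = if (n_pairs > 0L) mk(draw$aae, xAA, targets["AAE"], n_pairs) else NULL,
    ade = if (n_pairs > 0L) mk(draw$ade, xAD, targets["ADE"], n_pairs) else NULL,
    dae = if (n_pairs > 0L) mk(draw$dae, xDA, targets["DAE"], n_pairs) else NULL,
    dde = if (n_pairs > 0L) mk(draw$dde, xDD, targets["DDE"], n_pairs) else NULL,
    residual_sd = 1
  )
  attr(arch, "ref_geno") <- ref_geno
  arch
}
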