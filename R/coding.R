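#' Additive and dominance coefficients of a genotype code
#'
#' The full genetic model codes each locus with an additive contrast
#' \code{x_A} (1 for QQ, 0 for Qq, -1 for qq) and a dominance indicator
#' \code{x_D} (1 for Qq, 0 for QQ and qq).  Missing codes return NA for
#' both; downstream design construction imputes them (see
#' [build_design()]).
#'
#' @param code character vector of genotype codes in
#'   \code{c("QQ","Qq","qq", NA)}.
#' @return data.frame with columns \code{x_A} and \code{x_D}.
#' @examples
#' encode_locus(c("QQ", "Qq", "qq"))
#' @export
encode_locus <- function(code) {
  .check_codes(code)
  xa <- ifelse(code == "QQ", 1, ifelse(code == "qq", -1, 0))
  xd <- ifelse(code == "Qq", 1, 0)
  data.frame(x_A = as.numeric(xa), x_D = as.numeric(xd))
}

#' Digenic epistasis coefficients of a genotype pair
#'
#' Epistasis contrasts are products of constraint patterns on the two loci:
#' \code{x_AA} is 1 for QQxQQ and qqxqq, -1 for QQxqq and qqxQQ, else 0;
#' \code{x_AD} is 1 for QQxQq, -1 for qqxQq, else 0; \code{x_DA} is 1 for
#' QqxQQ, -1 for Qqxqq, else 0; \code{x_DD} is 1 for QqxQq, else 0.  These
#' equal the products \code{x_A(i)x_A(j)}, \code{x_A(i)x_D(j)},
#' \code{x_D(i)x_A(j)} and \code{x_D(i)x_D(j)} of the single-locus
#' contrasts.
#'
#' @param code_i,code_j genotype codes of the first and second locus.
#' @return data.frame with columns \code{x_AA}, \code{x_AD}, \code{x_DA},
#'   \code{x_DD}.
#' @examples
#' encode_epistasis("QQ", "qq")   # x_AA = -1
#' encode_epistasis("Qq", "Qq")   # x_DD = 1
#' @export
encode_epistasis <- function(code_i, code_j) {
  ci <- encode_locus(code_i)
  cj <- encode_locus(code_j)
  data.frame(
    x_AA = ci$x_A * cj$x_A,
    x_AD = ci$x_A * cj$x_D,
    x_DA = ci$x_D * cj$x_A,
    x_DD = ci$x_D * cj$x_D
  )
}

# line-level coefficient matrices ------------------------------------------

#' Per-line coefficient matrices for a set of loci
#'
#' Computes the x_A and x_D coefficient matrices (lines x loci) for the
#' given loci.  Missing genotype codes are imputed with the mean
#' coefficient of the locus within the line's family (keeping rows usable
#' after QC); loci or families with no observed calls fall back to the
#' overall locus mean, then 0.
#'
#' @param geno a [geno_matrix()].
#' @param loci character vector of SNP ids (default: all).
#' @return list with numeric matrices \code{xA}, \code{xD} (lines x loci).
#' @export
locus_coefficients <- function(geno, loci = geno$snps$snp) {
  missing_loci <- setdiff(loci, colnames(geno$codes))
  if (length(missing_loci) > 0L) {
    stop("loci absent from genotype matrix: ",
         paste(head(missing_loci, 5L), collapse = ", "), call. = FALSE)
  }
  codes <- geno$codes[, loci, drop = FALSE]
  xA <- matrix(NA_real_, nrow(codes), ncol(codes), dimnames = dimnames(codes))
  xA[codes == "QQ"] <- 1
  xA[codes == "Qq"] <- 0
  xA[codes == "qq"] <- -1
  xD <- matrix(NA_real_, nrow(codes), ncol(codes), dimnames = dimnames(codes))
  xD[codes == "Qq"] <- 1
  xD[codes %in% c("QQ", "qq")] <- 0
  fam <- geno$families
  impute <- function(m) {
    if (!anyNA(m)) return(m)
    for (j in seq_len(ncol(m))) {
      nas <- which(is.na(m[, j]))
      if (length(nas) == 0L) next
      fm <- tapply(m[, j], fam, mean, na.rm = TRUE)
      fill <- fm[fam[nas]]
      overall <- mean(m[, j], na.rm = TRUE)
      fill[!is.finite(fill)] <- overall
      fill[!is.finite(fill)] <- 0
      m[nas, j] <- fill
    }
    m
  }
  list(xA = impute(xA), xD = impute(xD))
}

#' @keywords internal
pair_coefficients <- function(coefs, pairs) {
  # products of imputed single-locus contrasts, one matrix per epistasis type
  n <- nrow(coefs$xA)
  np <- nrow(pairs)
  out <- list(
    xAA = matrix(0, n, np), xAD = matrix(0, n, np),
    xDA = matrix(0, n, np), xDD = matrix(0, n, np)
  )
  for (p in seq_len(np)) {
    ai <- coefs$xA[, pairs$snp1[p]]; di <- coefs$xD[, pairs$snp1[p]]
    aj <- coefs$xA[, pairs$snp2[p]]; dj <- coefs$xD[, pairs$snp2[p]]
    out$xAA[, p] <- ai * aj
    out$xAD[, p] <- ai * dj
    out$xDA[, p] <- di * aj
    out$xDD[, p] <- di * dj
  }
  pn <- paste(pairs$snp1, pairs$snp2, sep = "x")
  for (nm in names(out)) colnames(out[[nm]]) <- pn
  out
}

#' Principal components of population structure
#'
#' Computes the top-k principal component scores of the centered additive
#' coefficient matrix (lines x SNPs), used as model cofactors c_hk to
#' adjust for family structure.  Missing coefficients are imputed by the
#' column mean before centering.  The sign of each component is fixed by
#' convention: the loading with the largest magnitude is made positive.
#'
#' @param geno a [geno_matrix()].
#' @param k number of components, \code{0 <= k < min(lines, SNPs)}; k = 0
#'   returns an empty score matrix (the base, unadjusted model).
#' @return numeric matrix (lines x k) of PC scores; row names are line ids.
#' @export
compute_pcs <- function(geno, k) {
  k <- .check_count(k, "k", min = 0L)
  n <- nrow(geno$codes)
  m <- ncol(geno$codes)
  if (k >= min(n, m)) {
    stop("`k` must be smaller than min(number of lines, number of SNPs)",
         call. = FALSE)
  }
  if (k == 0L) {
    return(matrix(numeric(0), nrow = n, ncol = 0L,
                  dimnames = list(geno$lines, NULL)))
  }
  xA <- locus_coefficients(geno)$xA
  pc <- prcomp(xA, center = TRUE, scale. = FALSE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- geno$lines
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Build design matrices for the full genetic model
#'
#' Expands genotype codes into the fixed-effect coefficient columns and the
#' random-effect incidence blocks of the full model, with one row per
#' phenotype record.  Fixed columns are \code{a@snp}, \code{d@snp} per
#' locus and \code{aa@pair} ... \code{dd@pair} per pair.  Random blocks are
#' the environment indicator (for e_h) and, for every interaction family
#' (AE, DE, AAE, ADE, DAE, DDE), one column per term x environment holding
#' the fixed coefficient masked by environment membership.
#'
#' @param geno a [geno_matrix()].
#' @param pheno a [pheno_table()]; every line must be genotyped.
#' @param loci character vector of SNP ids entering the model.
#' @param pairs data.frame with columns \code{snp1}, \code{snp2} (may be
#'   NULL or empty).
#' @param n_pcs number of principal-component cofactor columns (0 = base
#'   model).
#' @return object of class \code{design_matrices}: list with \code{X}
#'   (fixed columns), \code{C} (cofactors), \code{Z} (named list of random
#'   incidence blocks, \code{env} first), \code{term_type} (named character
#'   vector typing every fixed column), \code{envs}, \code{records} (the
#'   aligned phenotype table), \code{loci}, \code{pairs}.
#' @export
build_design <- function(geno, pheno, loci, pairs = NULL, n_pcs = 0) {
  stopifnot(inherits(pheno, "data.frame"))
  absent <- setdiff(unique(pheno$line), geno$lines)
  if (length(absent) > 0L) {
    stop("phenotype lines absent from genotypes: ",
         paste(head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  if (is.null(pairs) || nrow(as.data.frame(pairs)) == 0L) {
    pairs <- data.frame(snp1 = character(), snp2 = character(),
                        stringsAsFactors = FALSE)
  }
  coefs <- locus_coefficients(geno, union(loci, c(pairs$snp1, pairs$snp2)))
  idx <- match(pheno$line, rownames(coefs$xA))

  Xa <- coefs$xA[idx, loci, drop = FALSE]
  Xd <- coefs$xD[idx, loci, drop = FALSE]
  if (length(loci) > 0L) {
    colnames(Xa) <- paste0("a@", loci)
    colnames(Xd) <- paste0("d@", loci)
  }
  X <- cbind(Xa, Xd)
  term_type <- setNames(rep(c("a", "d"), each = length(loci)), colnames(X))

  if (nrow(pairs) > 0L) {
    pc <- pair_coefficients(coefs, pairs)
    ep <- cbind(pc$xAA[idx, , drop = FALSE], pc$xAD[idx, , drop = FALSE],
                pc$xDA[idx, , drop = FALSE], pc$xDD[idx, , drop = FALSE])
    pn <- paste(pairs$snp1, pairs$snp2, sep = "x")
    colnames(ep) <- c(paste0("aa@", pn), paste0("ad@", pn),
                      paste0("da@", pn), paste0("dd@", pn))
    X <- cbind(X, ep)
    term_type <- c(term_type,
                   setNames(rep(c("aa", "ad", "da", "dd"), each = nrow(pairs)),
                            colnames(ep)))
  }

  envs <- sort(unique(pheno$env))
  Zenv <- matrix(0, nrow(pheno), length(envs),
                 dimnames = list(NULL, paste0("env", envs)))
  for (h in seq_along(envs)) Zenv[pheno$env == envs[h], h] <- 1

  mask_block <- function(cols, prefix) {
    # one column per term x environment: fixed coefficient inside env h, 0 outside
    out <- matrix(0, nrow(pheno), ncol(cols) * length(envs))
    cn <- character(ncol(out))
    k <- 0L
    for (j in seq_len(ncol(cols))) {
      for (h in seq_along(envs)) {
        k <- k + 1L
        out[, k] <- cols[, j] * Zenv[, h]
        cn[k] <- paste0(prefix, "@", sub("^[a-z]+@", "", colnames(cols)[j]),
                        ":env", envs[h])
      }
    }
    colnames(out) <- cn
    out
  }

  Z <- list(env = Zenv)
  Z$AE <- mask_block(Xa, "ae")
  Z$DE <- mask_block(Xd, "de")
  if (nrow(pairs) > 0L) {
    pn <- paste(pairs$snp1, pairs$snp2, sep = "x")
    aa <- X[, paste0("aa@", pn), drop = FALSE]
    ad <- X[, paste0("ad@", pn), drop = FALSE]
    da <- X[, paste0("da@", pn), drop = FALSE]
    dd <- X[, paste0("dd@", pn), drop = FALSE]
    Z$AAE <- mask_block(aa, "aae")
    Z$ADE <- mask_block(ad, "ade")
    Z$DAE <- mask_block(da, "dae")
    Z$DDE <- mask_block(dd, "dde")
  }

  n_pcs <- .check_count(n_pcs, "n_pcs", min = 0L)
  C <- if (n_pcs > 0L) {
    compute_pcs(geno, n_pcs)[idx, , drop = FALSE]
  } else {
    matrix(numeric(0), nrow = nrow(pheno), ncol = 0L)
  }

  structure(
    list(X = X, C = C, Z = Z, term_type = term_type, envs = envs,
         records = pheno, loci = loci, pairs = pairs),
    class = "design_matrices"
  )
}

#' @export
print.design_matrices <- function(x, ...) {
  cat(sprintf(
    "design_matrices: %d records, %d fixed columns, %d cofactors, random blocks: %s\n",
    nrow(x$X), ncol(x$X), ncol(x$C),
    paste(sprintf("%s(%d)", names(x$Z), vapply(x$Z, ncol, 0L)), collapse = ", ")))
  invisible(x)
}

#' Write design matrices as TSV for audit
#'
#' One row per phenotype record: the record keys, fixed-effect columns,
#' cofactors and every random incidence column.
#'
#' @param dm a [build_design()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_design_matrices <- function(dm, path) {
  out <- cbind(
    dm$records[, c("line", "env")],
    as.data.frame(dm$X),
    as.data.frame(dm$C),
    as.data.frame(do.call(cbind, unname(dm$Z)))
  )
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
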