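#' Total genotypic value of a multi-locus genotype combination
#'
#' Evaluates the full genetic model at a genotype vector: the sum of
#' additive, dominance and digenic epistasis contributions of the effect
#' set (and, when \code{env} is given, the environment-specific ae/de/
#' aae/ade/dae/dde deviations of that environment).  The population mean
#' is not included: values are expressed as G relative to the mean, with
#' per-environment means reported separately by
#' [predict_breeding_table()].
#'
#' @param genotype_vector named character vector of codes
#'   (\code{QQ/Qq/qq}) covering every locus of the effect set.
#' @param arch a [genetic_architecture()] (ground truth or estimated
#'   effect set, e.g. from [effects_to_architecture()]).
#' @param env environment index for environment-specific values, or NULL
#'   for the overall (main effects only) value.
#' @return total genotypic value (trait units).
#' @examples
#' arch <- genetic_architecture(
#'   loci = data.frame(snp = c("S1_1", "S2_1"), a = c(1, 2), d = 0),
#'   pairs = data.frame(snp1 = "S1_1", snp2 = "S2_1",
#'                      aa = 0.5, ad = 0, da = 0, dd = 0))
#' genotypic_value(c(S1_1 = "QQ", S2_1 = "qq"), arch)  # 1 - 2 - 0.5 = -1.5
#' @export
genotypic_value <- function(genotype_vector, arch, env = NULL) {
  missing_loci <- setdiff(arch$loci$snp, names(genotype_vector))
  if (length(missing_loci) > 0L) {
    stop("genotype vector misses loci: ",
         paste(head(missing_loci, 5L), collapse = ", "), call. = FALSE)
  }
  m <- matrix(genotype_vector[arch$loci$snp], nrow = 1,
              dimnames = list(NULL, arch$loci$snp))
  drop(.eval_combos(m, arch, env))
}

# vectorized evaluation of many genotype combinations (rows) at once
.eval_combos <- function(codes, arch, env = NULL) {
  .check_codes(codes)
  loci <- arch$loci$snp
  xA <- (codes == "QQ") - (codes == "qq")
  xD <- (codes == "Qq") * 1
  storage.mode(xA) <- storage.mode(xD) <- "double"
  i1 <- match(arch$pairs$snp1, loci)
  i2 <- match(arch$pairs$snp2, loci)

  a <- arch$loci$a; d <- arch$loci$d
  aa <- arch$pairs$aa; ad <- arch$pairs$ad
  da <- arch$pairs$da; dd <- arch$pairs$dd
  if (!is.null(env)) {
    if (!is.null(arch$ae)) a <- a + arch$ae[, env]
    if (!is.null(arch$de)) d <- d + arch$de[, env]
    if (!is.null(arch$aae)) aa <- aa + arch$aae[, env]
    if (!is.null(arch$ade)) ad <- ad + arch$ade[, env]
    if (!is.null(arch$dae)) da <- da + arch$dae[, env]
    if (!is.null(arch$dde)) dd <- dd + arch$dde[, env]
  }
  v <- drop(xA %*% a) + drop(xD %*% d)
  if (length(i1) > 0L) {
    v <- v +
      drop((xA[, i1, drop = FALSE] * xA[, i2, drop = FALSE]) %*% aa) +
      drop((xA[, i1, drop = FALSE] * xD[, i2, drop = FALSE]) %*% ad) +
      drop((xD[, i1, drop = FALSE] * xA[, i2, drop = FALSE]) %*% da) +
      drop((xD[, i1, drop = FALSE] * xD[, i2, drop = FALSE]) %*% dd)
  }
  v
}

#' Best existing line by predicted total genotypic value
#'
#' Evaluates every genotyped line under the effect set and returns the
#' line with the maximum value, overall (main effects) and per
#' environment (main plus environment-specific deviations).  Ties are
#' broken by line id order and reported in the result.
#'
#' @param geno a [geno_matrix()].
#' @param arch the effect set ([genetic_architecture()]).
#' @param envs environment indices to evaluate (default: all in the
#'   effect set).
#' @return data.frame with columns \code{scope} ("overall" or
#'   \code{"env<h>"}), \code{line}, \code{value}, \code{tied} (number of
#'   tied lines).
#' @export
best_existing_line <- function(geno, arch, envs = seq_len(n_envs_of(arch))) {
  if (length(geno$lines) == 0L) stop("no lines in genotype matrix", call. = FALSE)
  pick <- function(values, scope) {
    best <- max(values)
    ties <- geno$lines[values == best]
    ties <- ties[order(ties)]
    data.frame(scope = scope, line = ties[1L], value = best,
               tied = length(ties), stringsAsFactors = FALSE)
  }
  out <- pick(genotypic_value_lines(geno, arch, env = NULL), "overall")
  for (h in envs) {
    out <- rbind(out, pick(genotypic_value_lines(geno, arch, env = h),
                           paste0("env", h)))
  }
  rownames(out) <- NULL
  out
}

#' Exact optimum genotype combination by enumeration
#'
#' Exhaustively evaluates every combination of the allowed codes over the
#' effect set's loci and returns the maximizing genotype vector.  The
#' search space has \code{length(allowed_codes)^n_loci} points; above
#' \code{max_loci} loci the function refuses and directs to
#' [stepwise_tune()].  Evaluation is chunked so memory stays bounded.
#' Ties are resolved to the first combination in enumeration order
#' (codes varying fastest at the first locus, in the order given by
#' \code{allowed_codes}).
#'
#' @param arch the effect set.
#' @param allowed_codes subset of \code{c("QQ","Qq","qq")}; homozygotes
#'   only for superior lines, all three for superior hybrids.
#' @param env environment index or NULL for the overall value.
#' @param max_loci refusal threshold (default 15).
#' @return list with \code{genotype} (named character vector) and
#'   \code{value}.
#' @export
enumerate_optimum <- function(arch, allowed_codes = c("QQ", "qq"),
                              env = NULL, max_loci = 15L) {
  allowed_codes <- match.arg(allowed_codes, GENO_CODES, several.ok = TRUE)
  loci <- arch$loci$snp
  n <- length(loci)
  if (n > max_loci) {
    stop("enumeration over ", n, " loci exceeds max_loci = ", max_loci,
         "; use stepwise_tune()", call. = FALSE)
  }
  n_comb <- length(allowed_codes)^n
  chunk <- 65536L
  best_val <- -Inf
  best_idx <- NA_integer_
  for (start in seq(0L, n_comb - 1L, by = chunk)) {
    ii <- start:min(start + chunk - 1L, n_comb - 1L)
    codes <- matrix("", length(ii), n, dimnames = list(NULL, loci))
    rem <- ii
    for (j in seq_len(n)) {
      codes[, j] <- allowed_codes[rem %% length(allowed_codes) + 1L]
      rem <- rem %/% length(allowed_codes)
    }
    vals <- .eval_combos(codes, arch, env)
    w <- which.max(vals)
    if (vals[w] > best_val) {
      best_val <- vals[w]
      best_combo <- codes[w, ]
    }
  }
  list(genotype = setNames(best_combo, loci), value = best_val)
}

#' Stepwise tuning of a genotype combination
#'
#' Coordinate-wise greedy search: loci are visited in sweeps ordered by
#' descending main-effect magnitude (|a| + |d|, ties by locus id), and at
#' each visit the locus is set to the allowed code that maximizes the
#' total genotypic value holding all other loci fixed.  Sweeps repeat
#' until no single-locus change improves the value or \code{max_sweeps}
#' is reached; the value is monotonically non-decreasing across sweeps
#' and the result is deterministic given the start vector.
#'
#' @param arch the effect set.
#' @param allowed_codes subset of \code{c("QQ","Qq","qq")}.
#' @param env environment index or NULL.
#' @param start_vector named genotype vector to start from; by default the
#'   search is restarted from several deterministic vectors (each locus's
#'   best code by main effects alone, and each uniform allowed code) and
#'   the best converged solution is returned.
#' @param max_sweeps sweep limit per start (default 50).
#' @return list with \code{genotype}, \code{value}, \code{sweeps}.
#' @export
stepwise_tune <- function(arch, allowed_codes = c("QQ", "qq"), env = NULL,
                          start_vector = NULL, max_sweeps = 50L) {
  allowed_codes <- match.arg(allowed_codes, GENO_CODES, several.ok = TRUE)
  loci <- arch$loci$snp
  if (is.null(start_vector)) {
    # deterministic multi-start: greedy main-effect vector plus every
    # uniform vector; coordinate ascent from each, keep the best
    a <- arch$loci$a; d <- arch$loci$d
    if (!is.null(env)) {
      if (!is.null(arch$ae)) a <- a + arch$ae[, env]
      if (!is.null(arch$de)) d <- d + arch$de[, env]
    }
    single <- vapply(seq_along(loci), function(i) {
      vals <- vapply(allowed_codes, function(cd)
        a[i] * ((cd == "QQ") - (cd == "qq")) + d[i] * (cd == "Qq"), 0)
      allowed_codes[which.max(vals)]
    }, "")
    starts <- c(list(setNames(single, loci)),
                lapply(allowed_codes, function(cd)
                  setNames(rep(cd, length(loci)), loci)))
    sols <- lapply(starts, function(sv)
      stepwise_tune(arch, allowed_codes, env, start_vector = sv,
                    max_sweeps = max_sweeps))
    best <- which.max(vapply(sols, `[[`, 0, "value"))
    return(sols[[best]])
  }
  if (!all(loci %in% names(start_vector))) {
    stop("start vector misses loci", call. = FALSE)
  }
  if (!all(start_vector[loci] %in% allowed_codes)) {
    stop("start vector uses codes outside `allowed_codes`", call. = FALSE)
  }
  cur <- start_vector[loci]
  order_idx <- order(-(abs(arch$loci$a) + abs(arch$loci$d)), loci)
  cur_val <- genotypic_value(cur, arch, env)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    improved <- FALSE
    for (i in order_idx) {
      cand <- matrix(rep(cur, each = length(allowed_codes)),
                     nrow = length(allowed_codes),
                     dimnames = list(NULL, loci))
      cand[, i] <- allowed_codes
      vals <- .eval_combos(cand, arch, env)
      w <- which.max(vals)
      if (vals[w] > cur_val + 1e-12) {
        cur[i] <- allowed_codes[w]
        cur_val <- vals[w]
        improved <- TRUE
      }
    }
    if (!improved || sweeps >= max_sweeps) break
  }
  list(genotype = cur, value = cur_val, sweeps = sweeps)
}

#' Breeding prediction table
#'
#' Assembles the breeding summary for an effect set: the estimated mean,
#' the all-QQ, all-qq and all-Qq (F1) combination values, the best
#' existing line, the predicted superior line (homozygous codes only) and
#' the predicted superior hybrid (homozygous and heterozygous codes),
#' overall and per environment.  The overall column uses main effects
#' only; environment columns add the environment-specific interaction
#' deviations.  Optimum searches use exact enumeration when the search
#' space is at most \code{enumerate_limit} combinations and stepwise
#' tuning otherwise; the hybrid search is seeded with the superior-line
#' solution, so the superior hybrid never falls below the superior line.
#'
#' @param arch the effect set ([genetic_architecture()]).
#' @param geno a [geno_matrix()] of existing lines.
#' @param envs environment indices (default: all in the effect set).
#' @param enumerate_limit maximum number of combinations for exact
#'   enumeration (default 20000).
#' @return object of class \code{breeding_prediction}: data.frame with
#'   rows mu, QQ, qq, F1, best_line, superior_line, superior_hybrid and
#'   one column per scope (\code{G}, \code{G_GE1}, ...).  Attributes
#'   \code{best_lines} (ids per scope), \code{superior_line_genotypes}
#'   and \code{superior_hybrid_genotypes} (named code vectors per scope).
#' @export
predict_breeding_table <- function(arch, geno,
                                   envs = seq_len(n_envs_of(arch)),
                                   enumerate_limit = 20000L) {
  if (nrow(arch$loci) == 0L) stop("effect set is empty", call. = FALSE)
  loci <- arch$loci$snp
  n <- length(loci)
  uniform <- function(code) setNames(rep(code, n), loci)

  optimum <- function(allowed, env, start = NULL) {
    if (length(allowed)^n <= enumerate_limit) {
      enumerate_optimum(arch, allowed, env, max_loci = n)
    } else {
      stepwise_tune(arch, allowed, env, start_vector = start)
    }
  }

  scopes <- c("G", paste0("G_GE", envs))
  env_of <- c(list(NULL), as.list(envs))
  bl <- best_existing_line(geno, arch, envs)

  tab <- matrix(NA_real_, 7L, length(scopes),
                dimnames = list(c("mu", "QQ", "qq", "F1", "best_line",
                                  "superior_line", "superior_hybrid"), scopes))
  best_ids <- character(length(scopes))
  sl_geno <- sh_geno <- vector("list", length(scopes))
  names(sl_geno) <- names(sh_geno) <- scopes

  for (s in seq_along(scopes)) {
    env <- env_of[[s]]
    tab["mu", s] <- arch$mu +
      if (!is.null(env) && !is.null(arch$env_effects)) arch$env_effects[env] else 0
    tab["QQ", s] <- genotypic_value(uniform("QQ"), arch, env)
    tab["qq", s] <- genotypic_value(uniform("qq"), arch, env)
    tab["F1", s] <- genotypic_value(uniform("Qq"), arch, env)
    tab["best_line", s] <- bl$value[s]
    best_ids[s] <- bl$line[s]
    sl <- optimum(c("QQ", "qq"), env)
    sh <- optimum(GENO_CODES, env, start = sl$genotype)
    if (sh$value < sl$value) sh <- sl  # hybrid space contains the line space
    tab["superior_line", s] <- sl$value
    tab["superior_hybrid", s] <- sh$value
    sl_geno[[s]] <- sl$genotype
    sh_geno[[s]] <- sh$genotype
  }

  out <- as.data.frame(tab)
  out <- cbind(entry = rownames(tab), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out,
            best_lines = setNames(best_ids, scopes),
            superior_line_genotypes = sl_geno,
            superior_hybrid_genotypes = sh_geno,
            class = c("breeding_prediction", "data.frame"))
}

#' @export
print.breeding_prediction <- function(x, ...) {
  cat("breeding prediction (values are G relative to the mean; mu row absolute):\n")
  df <- as.data.frame(unclass(x))
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a breeding prediction table as TSV
#'
#' Writes the value table followed by the superior line / hybrid genotype
#' vectors (one row per SNP and scope).
#'
#' @param bp a \code{breeding_prediction}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_breeding_table <- function(bp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write.table(as.data.frame(unclass(bp)), con, sep = "\t",
              row.names = FALSE, quote = FALSE)
  writeLines("", con)
  sl <- attr(bp, "superior_line_genotypes")
  sh <- attr(bp, "superior_hybrid_genotypes")
  writeLines("kind\tscope\tsnp\tcode", con)
  for (s in names(sl)) {
    writeLines(sprintf("superior_line\t%s\t%s\t%s", s, names(sl[[s]]), sl[[s]]), con)
    writeLines(sprintf("superior_hybrid\t%s\t%s\t%s", s, names(sh[[s]]), sh[[s]]), con)
  }
  invisible(path)
}
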