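#' Aggregate component heritabilities
#'
#' Computes the three aggregate heritabilities from the twelve component
#' shares of the full genetic model: the total \code{h2_T} (sum of every
#' component), the dominance-related aggregate \code{h2_Dplus}
#' (\code{D + AD + DA + DD + DE + ADE + DAE + DDE}) and the
#' gene-by-environment aggregate \code{h2_GE}
#' (\code{AE + DE + AAE + ADE + DAE + DDE}).  Components absent from the
#' input count as zero; values can be fractions or percent (the aggregates
#' are on the same scale as the input).
#'
#' @param components named numeric vector with names among
#'   \code{A, D, AA, AD, DA, DD, AE, DE, AAE, ADE, DAE, DDE}.
#' @return named numeric vector \code{c(h2_T, h2_Dplus, h2_GE)}.
#' @examples
#' aggregate_heritability(c(A = 11.6, D = 9.43, AE = 11.65, DE = 4.63))
#' @export
aggregate_heritability <- function(components) {
  valid <- c("A", "D", "AA", "AD", "DA", "DD",
             "AE", "DE", "AAE", "ADE", "DAE", "DDE")
  if (is.null(names(components)) || !all(names(components) %in% valid)) {
    stop("`components` must be named with components among: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  x <- setNames(rep(0, length(valid)), valid)
  x[names(components)] <- components
  c(h2_T = sum(x),
    h2_Dplus = sum(x[c("D", "AD", "DA", "DD", "DE", "ADE", "DAE", "DDE")]),
    h2_GE = sum(x[c("AE", "DE", "AAE", "ADE", "DAE", "DDE")]))
}

#' Partition heritability by genetic-effect component
#'
#' Computes the variance share of every term family of the full genetic
#' model: for each component (A, D, AA, AD, DA, DD and the interaction
#' families AE ... DDE) the predicted contribution of its terms across
#' the observed records is formed from the estimated effects, and the
#' component heritability is the variance of that contribution divided by
#' the total phenotypic variance.  Results are reported in percent,
#' together with the aggregates of [aggregate_heritability()].
#'
#' @param estimates an \code{effect_estimates} from [gibbs_estimate()]
#'   (posterior means are used), or any data.frame with \code{term} and
#'   \code{estimate}.
#' @param dm the matching \code{design_matrices}.
#' @param y phenotype values (defaults to the design's records).
#' @return object of class \code{herit_table}: data.frame with one row per
#'   component (\code{component}, \code{h2_pct}) and attributes
#'   \code{aggregates} (percent) and \code{total_variance}.
#' @export
heritability <- function(estimates, dm, y = dm$records$value) {
  vp <- var(y)
  if (!is.finite(vp) || vp <= 0) {
    stop("total phenotypic variance is zero; heritability undefined",
         call. = FALSE)
  }
  est <- setNames(estimates$estimate, estimates$term)
  share <- function(M) {
    cols <- intersect(colnames(M), names(est))
    if (length(cols) == 0L) return(0)
    contrib <- drop(M[, cols, drop = FALSE] %*% est[cols])
    100 * var(contrib) / vp
  }
  fixed_types <- c(A = "a", D = "d", AA = "aa", AD = "ad", DA = "da", DD = "dd")
  comp <- vapply(fixed_types, function(tt) {
    share(dm$X[, dm$term_type == tt, drop = FALSE])
  }, 0)
  names(comp) <- names(fixed_types)
  rand_map <- c(AE = "AE", DE = "DE", AAE = "AAE", ADE = "ADE",
                DAE = "DAE", DDE = "DDE")
  for (nm in names(rand_map)) {
    comp[nm] <- if (rand_map[nm] %in% names(dm$Z)) share(dm$Z[[rand_map[nm]]]) else 0
  }
  agg <- aggregate_heritability(comp)
  structure(
    data.frame(component = names(comp), h2_pct = unname(comp),
               stringsAsFactors = FALSE),
    aggregates = agg, total_variance = vp,
    class = c("herit_table", "data.frame")
  )
}

#' @export
print.herit_table <- function(x, ...) {
  cat("heritability components (% of phenotypic variance):\n")
  print(data.frame(component = x$component, h2_pct = round(x$h2_pct, 2)),
        row.names = FALSE)
  agg <- attr(x, "aggregates")
  cat(sprintf("aggregates: h2_T = %.2f, h2_D+ = %.2f, h2_GE = %.2f\n",
              agg["h2_T"], agg["h2_Dplus"], agg["h2_GE"]))
  invisible(x)
}

#' Write a heritability table as TSV
#'
#' @param ht a \code{herit_table}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_herit_table <- function(ht, path) {
  agg <- attr(ht, "aggregates")
  df <- rbind(
    data.frame(component = ht$component, h2_pct = ht$h2_pct),
    data.frame(component = c("T", "Dplus", "GE"), h2_pct = unname(agg))
  )
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-environment effect matrix (heat-map style export)
#'
#' Builds the environment-specific total effect of every modeled term:
#' main effect plus the realized interaction deviation in each
#' environment, the layout used for location-specific effect heat maps.
#'
#' @param estimates an \code{effect_estimates}.
#' @param dm the matching \code{design_matrices}.
#' @return data.frame with columns \code{term}, \code{type} and one
#'   \code{env<h>} column per environment.
#' @export
per_env_effects <- function(estimates, dm) {
  est <- setNames(estimates$estimate, estimates$term)
  get1 <- function(nm) if (nm %in% names(est)) unname(est[nm]) else 0
  envs <- dm$envs
  main_terms <- colnames(dm$X)
  gxe_prefix <- c(a = "ae", d = "de", aa = "aae", ad = "ade",
                  da = "dae", dd = "dde")
  rows <- lapply(main_terms, function(tm) {
    tt <- sub("@.*$", "", tm)
    id <- sub("^[a-z]+@", "", tm)
    vals <- vapply(envs, function(h)
      get1(tm) + get1(paste0(gxe_prefix[tt], "@", id, ":env", h)), 0)
    out <- data.frame(term = tm, type = tt, stringsAsFactors = FALSE)
    out[paste0("env", envs)] <- as.list(vals)
    out
  })
  do.call(rbind, rows)
}
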