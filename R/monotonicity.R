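#' Single-allele substitution effects at a locus
#'
#' For every genetic background of locus `k`, the two substitution effects
#' are `G(..12..) - G(..11..)` and `G(..22..) - G(..12..)`: the change in
#' genotypic value from replacing one allele at locus `k` with the background
#' fixed. The map is monotone with respect to locus `k` exactly when all
#' `2 * 3^(N-1)` effects are non-negative.
#'
#' @param gpmap a [gpmap].
#' @param locus locus index in `1..N`.
#' @return numeric vector of length `2 * 3^(N-1)`: for each background in
#'   canonical index order, first the `12-11` effect, then the `22-12`
#'   effect.
#' @examples
#' substitution_effects(catalog_map("mouseweight"), 1)
#' @export
substitution_effects <- function(gpmap, locus) {
  g <- as_gpmap(gpmap)
  check_locus(g, locus)
  effects <- numeric(0)
  for (bg in locus_backgrounds(g$n_loci, locus)) {
    v <- g$values[bg]
    effects <- c(effects, v[2] - v[1], v[3] - v[2])
  }
  effects
}

#' Default zero tolerance for substitution effects
#'
#' Effects with magnitude at or below the tolerance are treated as exactly
#' zero (neither positive nor negative), which keeps solver noise in
#' ODE-derived maps from flipping sign classifications. Default:
#' `1e-9 * (max - min)` of the genotypic values.
#'
#' @param gpmap a [gpmap].
#' @return non-negative scalar in trait units.
#' @export
default_zero_tol <- function(gpmap) {
  g <- as_gpmap(gpmap)
  1e-9 * diff(range(g$values))
}

#' Per-locus degree of monotonicity
#'
#' Splits the locus-`k` substitution effects by sign into the sum of positive
#' effects `P_k` and the sum of magnitudes of negative effects `N_k`, with
#' `T_k = P_k + N_k`, and returns the degree of monotonicity
#' `m_k = |P_k - N_k| / T_k`. `m_k = 1` means all non-zero effects share one
#' sign (order-preserving); `m_k = 0` means positive and negative effects
#' balance exactly (completely order-breaking).
#'
#' @inheritParams substitution_effects
#' @param zero_tol effects with `|s| <= zero_tol` are excluded from both sign
#'   sets; default [default_zero_tol()].
#' @return list with `P`, `N`, `T`, `m` (`m` is `NA` when `T = 0`, i.e. the
#'   locus carries no variation).
#' @examples
#' locus_monotonicity(catalog_map("mouseweight"), 1)  # P 10.50, N 0.77
#' @export
locus_monotonicity <- function(gpmap, locus, zero_tol = NULL) {
  g <- as_gpmap(gpmap)
  if (is.null(zero_tol)) zero_tol <- default_zero_tol(g)
  stopifnot(zero_tol >= 0)
  s <- substitution_effects(g, locus)
  s[abs(s) <= zero_tol] <- 0
  P <- sum(s[s > 0])
  N <- -sum(s[s < 0])
  T <- P + N
  list(P = P, N = N, T = T, m = if (T > 0) abs(P - N) / T else NA_real_)
}

#' Degree of monotonicity of a GP map
#'
#' The overall degree of monotonicity `m` is the weighted mean of the
#' per-locus degrees `m_k`, weighted by the total absolute substitution
#' effect `T_k` of each locus, so loci with larger effects dominate. `m = 1`
#' for order-preserving maps, `m = 0` for purely non-monotone maps (pure
#' overdominance, pure epistasis), intermediate otherwise.
#'
#' Allele orientation is applied first by default; `m`, `m_k` and the
#' order-breaking flags are all invariant to allele relabelling, so this
#' only fixes the sign convention under which the per-locus `P` and `N`
#' sums are reported.
#'
#' @inheritParams locus_monotonicity
#' @param orient apply [orient_alleles()] before computing flags.
#' @return object of class `monotonicity_report`: list with overall degree
#'   `m` (`NA` with a warning flag for a completely flat map), `per_locus`
#'   data frame (`locus`, `P`, `N`, `T`, `m`, `monotone`),
#'   `order_breaking_count`, `zero_tol`, `flat`.
#' @examples
#' degree_of_monotonicity(catalog_map("mouseweight"))  # m about 0.79
#' @export
degree_of_monotonicity <- function(gpmap, zero_tol = NULL, orient = TRUE) {
  g <- as_gpmap(gpmap)
  if (is.null(zero_tol)) zero_tol <- default_zero_tol(g)
  if (orient) g <- orient_alleles(g)$map
  per <- lapply(seq_len(g$n_loci), function(k) {
    lm <- locus_monotonicity(g, k, zero_tol = zero_tol)
    lm$monotone <- is_monotone_locus(g, k, zero_tol = zero_tol)
    lm
  })
  df <- data.frame(locus = seq_len(g$n_loci),
                   P = vapply(per, `[[`, 0, "P"),
                   N = vapply(per, `[[`, 0, "N"),
                   T = vapply(per, `[[`, 0, "T"),
                   m = vapply(per, `[[`, 0, "m"),
                   monotone = vapply(per, `[[`, TRUE, "monotone"))
  active <- df$T > 0
  flat <- !any(active)
  if (flat) {
    warning("flat GP map: degree of monotonicity is undefined")
    m <- NA_real_
  } else {
    m <- sum(df$m[active] * df$T[active]) / sum(df$T[active])
  }
  structure(list(m = m, per_locus = df,
                 order_breaking_count = sum(!df$monotone),
                 zero_tol = zero_tol, flat = flat),
            class = "monotonicity_report")
}

#' @export
print.monotonicity_report <- function(x, digits = 4, ...) {
  cat("Degree of monotonicity: m =", format(x$m, digits = digits), "\n")
  if (x$flat) cat("  (flat map: m undefined)\n")
  df <- x$per_locus
  df$P <- round(df$P, digits); df$N <- round(df$N, digits)
  df$T <- round(df$T, digits); df$m <- round(df$m, digits)
  print(df, row.names = FALSE)
  cat("Order-breaking with respect to", x$order_breaking_count, "of",
      nrow(df), "loci\n")
  invisible(x)
}

#' Is a GP map monotone with respect to a locus?
#'
#' A map is monotone (order-preserving) with respect to locus `k` when the
#' genotypic value is non-decreasing along `11 -> 12 -> 22` at locus `k` in
#' every genetic background, for allele labels chosen per the orientation
#' convention; non-strict inequalities admit complete dominance and
#' magnitude epistasis. Since relabelling the alleles of locus `k` maps each
#' substitution effect to minus its partner, the flag reduces to a
#' label-free criterion: monotone iff all locus-`k` effects beyond
#' `zero_tol` share one sign, which is exactly `m_k = 1`. (A global
#' orientation via the minimal homozygote can tie-break arbitrarily on maps
#' with saturated flat corners, so the flag is computed sign-symmetrically
#' rather than from a fixed orientation.)
#'
#' @inheritParams locus_monotonicity
#' @return logical; invariant to allele relabelling at any locus.
#' @export
is_monotone_locus <- function(gpmap, locus, zero_tol = NULL) {
  g <- as_gpmap(gpmap)
  if (is.null(zero_tol)) zero_tol <- default_zero_tol(g)
  s <- substitution_effects(g, locus)
  s[abs(s) <= zero_tol] <- 0
  all(s >= 0) || all(s <= 0)
}

#' Number of loci a GP map is order-breaking for
#'
#' @inheritParams is_monotone_locus
#' @return integer in `0..N`: the number of loci failing
#'   [is_monotone_locus()].
#' @export
order_breaking_count <- function(gpmap, zero_tol = NULL) {
  g <- as_gpmap(gpmap)
  if (is.null(zero_tol)) zero_tol <- default_zero_tol(g)
  sum(!vapply(seq_len(g$n_loci), function(k)
    is_monotone_locus(g, k, zero_tol = zero_tol), TRUE))
}
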