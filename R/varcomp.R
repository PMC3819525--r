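#' Orthogonal design matrix for equal-frequency variance decomposition
#'
#' Builds the `3^N x 3^N` design matrix of the statistical (equal genotype
#' frequency) decomposition of genotypic values: the Kronecker products,
#' across loci, of the per-locus basis consisting of the intercept `(1,1,1)`,
#' the additive contrast `(-1,0,1)` (centred 2-allele content) and the
#' dominance contrast `(-1,2,-1)` (orthogonal to both under equal weights).
#' Under equal genotype frequencies `1/3^N` this formulation coincides with
#' the unweighted regression of genotypic values on gene content, so the
#' columns are mutually orthogonal under the uniform inner product and the
#' decomposition is an orthogonal projection. Contrast scaling is immaterial:
#' variance components are projection variances, not raw coefficients.
#'
#' @param n_loci number of loci.
#' @return `3^N x 3^N` numeric matrix; columns named by the per-locus factor
#'   pattern (`.` intercept, `a` additive, `d` dominance; locus 1 first),
#'   e.g. `"a."` is the locus-1 additive term and `"ad"` the
#'   additive-by-dominance interaction.
#' @export
noia_design_matrix <- function(n_loci) {
  basis <- list(`.` = c(1, 1, 1), a = c(-1, 0, 1), d = c(-1, 2, -1))
  combos <- counts_matrix(n_loci) # reuse base-3 enumeration: 0=.,1=a,2=d
  sym <- c(".", "a", "d")
  cols <- apply(combos, 1, function(cc) {
    Reduce(kronecker, lapply(cc, function(s) basis[[s + 1L]]))
  })
  colnames(cols) <- apply(combos, 1, function(cc)
    paste(sym[cc + 1L], collapse = ""))
  cols
}

#' Additive, dominance and epistatic variance components of a GP map
#'
#' Decomposes a GP map into orthogonal additive, dominance and epistatic
#' components under equal genotype frequencies (`1/3^N`), the setting in
#' which the statistical and functional formulations and unweighted
#' regression all agree. Each term's effect is the least-squares projection
#' coefficient of the genotypic values on the corresponding orthogonal
#' column; its variance component is the population variance of that
#' projected column. The components sum exactly to the total genetic
#' variance `V_G` (the population variance of the `3^N` genotypic values),
#' and `V_A` is the sum over the single-locus additive terms only. The ratio
#' `V_A/V_G` measures how well an additive model describes the map: 1 for
#' the fully additive map, 0 for pure overdominance and pure epistasis.
#'
#' @param gpmap a [gpmap].
#' @return object of class `gp_varcomp`: list with `components` data frame
#'   (`term`, `type`, `order`, `effect`, `variance`), `V_A`, `V_G`, `ratio`
#'   (`NA` for a flat map), and `by_order` (variance aggregated by
#'   interaction order as a diagnostic).
#' @examples
#' variance_components(catalog_map("DD"))$ratio  # 0.375
#' @export
variance_components <- function(gpmap) {
  g <- as_gpmap(gpmap)
  X <- noia_design_matrix(g$n_loci)
  n <- length(g$values)
  ss <- colSums(X^2)
  effect <- as.numeric(crossprod(X, g$values)) / ss
  variance <- effect^2 * ss / n        # non-intercept columns have mean zero
  term <- colnames(X)
  n_nonadd <- vapply(strsplit(term, ""), function(ch) sum(ch != "."), 0L)
  n_a <- vapply(strsplit(term, ""), function(ch) sum(ch == "a"), 0L)
  type <- ifelse(n_nonadd == 0L, "intercept",
          ifelse(n_nonadd == 1L & n_a == 1L, "additive",
          ifelse(n_nonadd == 1L, "dominance", "epistasis")))
  variance[type == "intercept"] <- 0
  comp <- data.frame(term = term, type = type, order = n_nonadd,
                     effect = effect, variance = variance,
                     stringsAsFactors = FALSE)
  V_G <- sum(comp$variance)
  V_A <- sum(comp$variance[comp$type == "additive"])
  by_order <- stats::aggregate(variance ~ order, data = comp[comp$order > 0, ],
                               FUN = sum)
  structure(list(components = comp,
                 V_A = V_A, V_G = V_G,
                 ratio = if (V_G > 0) V_A / V_G else NA_real_,
                 by_order = by_order),
            class = "gp_varcomp")
}

#' @export
print.gp_varcomp <- function(x, digits = 4, ...) {
  cat("Equal-frequency variance decomposition\n")
  cat("  V_A =", format(x$V_A, digits = digits),
      " V_G =", format(x$V_G, digits = digits),
      " V_A/V_G =", format(x$ratio, digits = digits), "\n")
  comp <- x$components[x$components$order > 0 & x$components$variance > 0, ]
  if (nrow(comp)) {
    comp$effect <- round(comp$effect, digits)
    comp$variance <- round(comp$variance, digits + 2)
    print(comp, row.names = FALSE)
  }
  invisible(x)
}
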