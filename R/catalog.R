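#' Catalog of classical two-locus GP maps
#'
#' Canonical two-locus genotype-phenotype maps used throughout the
#' monotonicity literature: additive (A), partial dominance (PD), complete
#' dominance (CD), duplicate dominant epistasis (DD, the 15:1 pattern),
#' duplicate recessive genes (DR, 9:7), recessive epistasis (RE, 9:3:4),
#' pure overdominance (OD), and the pure epistasis maps additive-by-additive
#' (AxA), dominance-by-dominance (DxD) and additive-by-dominance (AxD).
#' `"mouseweight"` returns the published two-locus map for 10-week body
#' weight (grams) in a mouse F2 cross; all other maps are normalised to the
#' unit interval (both monotonicity measures and variance ratios are
#' scale-free, so the normalisation is immaterial).
#'
#' @param name one of `"A"`, `"PD"`, `"CD"`, `"DD"`, `"DR"`, `"RE"`, `"OD"`,
#'   `"AxA"`, `"DxD"`, `"AxD"`, `"mouseweight"`.
#' @return a two-locus [gpmap].
#' @examples
#' catalog_map("mouseweight")
#' degree_of_monotonicity(catalog_map("DD"))
#' @export
catalog_map <- function(name) {
  valid <- c("A", "PD", "CD", "DD", "DR", "RE", "OD", "AxA", "DxD", "AxD",
             "mouseweight")
  if (length(name) != 1L || !name %in% valid) {
    stop("unknown catalog map '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "))
  }
  if (name == "mouseweight") {
    return(gpmap(c(31.23, 34.13, 33.82,
                   34.89, 35.90, 36.53,
                   34.12, 37.95, 36.84), n_loci = 2))
  }
  cm <- counts_matrix(2L)
  i <- cm[, 1] + 1L  # locus-1 2-allele count + 1
  j <- cm[, 2] + 1L
  a <- c(-1, 0, 1)       # additive scores
  d <- c(-1, 1, -1)      # dominance scores
  values <- switch(name,
    A   = (cm[, 1] + cm[, 2]) / 4,
    PD  = (c(0, 0.75, 1)[i] + c(0, 0.75, 1)[j]) / 2,
    CD  = (c(0, 1, 1)[i] + c(0, 1, 1)[j]) / 2,
    DD  = ifelse(cm[, 1] == 0 & cm[, 2] == 0, 0, 1),
    DR  = ifelse(cm[, 1] > 0 & cm[, 2] > 0, 1, 0),
    RE  = ifelse(cm[, 1] == 0, 0, ifelse(cm[, 2] > 0, 1, 0.5)),
    OD  = (c(0, 1, 0)[i] + c(0, 1, 0)[j]) / 2,
    AxA = (a[i] * a[j] + 1) / 2,
    DxD = (d[i] * d[j] + 1) / 2,
    AxD = (a[i] * d[j] + 1) / 2)
  gpmap(values, n_loci = 2)
}

#' Random GP map with uniform genotypic values
#'
#' Draws the `3^N` genotypic values independently from the standard uniform
#' distribution, the random-map model used for the monotonicity-vs-additivity
#' scatter studies. Uses the current RNG state; call `set.seed()` first for
#' reproducibility.
#'
#' @param n_loci number of loci.
#' @return a [gpmap].
#' @export
random_gpmap <- function(n_loci) {
  gpmap(stats::runif(3^n_loci), n_loci = n_loci)
}

#' Rearrange genotypic values to be order-preserving for one locus
#'
#' Within every genetic background of locus `k`, sorts the three genotypic
#' values ascending in the 2-allele content of locus `k`. The multiset of
#' genotypic values is preserved; the result is monotone with respect to
#' locus `k` (all locus-`k` substitution effects non-negative). This is the
#' monotone-rearrangement variant used to contrast random maps with maps
#' forced to be order-preserving for one locus.
#'
#' @param gpmap a [gpmap].
#' @param locus locus index in `1..N`.
#' @return a [gpmap].
#' @export
rearrange_monotone <- function(gpmap, locus) {
  g <- as_gpmap(gpmap)
  check_locus(g, locus)
  values <- g$values
  for (bg in locus_backgrounds(g$n_loci, locus)) {
    values[bg] <- sort(values[bg])
  }
  gpmap(values, n_loci = g$n_loci)
}

check_locus <- function(g, locus) {
  if (length(locus) != 1L || is.na(locus) || locus < 1 || locus > g$n_loci) {
    stop("locus must be a single index in 1..", g$n_loci)
  }
  invisible(as.integer(locus))
}

# List of index triplets (R positions) for the three locus-k genotypes within
# each genetic background, backgrounds in canonical index order.
locus_backgrounds <- function(n_loci, locus) {
  step <- 3L^(n_loci - locus)
  cm <- counts_matrix(n_loci)
  base <- which(cm[, locus] == 0L)
  lapply(base, function(b) c(b, b + step, b + 2L * step))
}
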