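#' Line plot of a two- or three-locus GP map
#'
#' Standard GP-map line plot: the locus-1 genotype on the x axis
#' (`11, 12, 22`), one line per genetic background of locus 1, genotypic
#' value on the y axis. Order-breaking shows up as crossing or
#' non-increasing lines.
#'
#' @param x a [gpmap].
#' @param main plot title.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.gpmap <- function(x, main = "GP map", ...) {
  n_bg <- 3^(x$n_loci - 1L)
  vals <- matrix(NA_real_, nrow = 3, ncol = n_bg)
  bgs <- locus_backgrounds(x$n_loci, 1L)
  for (b in seq_along(bgs)) vals[, b] <- x$values[bgs[[b]]]
  graphics::matplot(1:3, vals, type = "b", pch = 16, lty = 1,
                    col = grDevices::hcl.colors(max(n_bg, 2), "Dark 3"),
                    xaxt = "n", xlab = "locus 1 genotype",
                    ylab = "genotypic value", main = main, ...)
  graphics::axis(1, at = 1:3, labels = c("11", "12", "22"))
  invisible(x)
}

#' Plot a monotone decomposition
#'
#' Three panels: the original map, its monotone component and the
#' non-monotone residual.
#'
#' @param x a [decompose_monotone()] result.
#' @param ... passed to [plot.gpmap()].
#' @return `x`, invisibly.
#' @export
plot.monotone_decomposition <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  plot(x$gpmap, main = "G", ...)
  plot(x$monotone, main = "G_M (monotone)", ...)
  plot(x$residual, main = "G_N (residual)", ...)
  invisible(x)
}
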