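#' Construct a genotype-phenotype map
#'
#' A GP map assigns a real genotypic value (the mean trait value) to each of
#' the `3^N` genotypes over `N` biallelic diploid loci. Values are stored in
#' canonical genotype order: the base-3 encoding of per-locus 2-allele counts
#' with locus 1 most significant, i.e. for two loci
#' `1111, 1112, 1122, 1211, 1212, 1222, 2211, 2212, 2222`.
#'
#' @param values numeric vector of `3^N` finite genotypic values in canonical
#'   order (trait units, arbitrary).
#' @param n_loci number of loci `N`; inferred from `length(values)` when `NULL`.
#' @param labels optional per-genotype labels; defaults to the canonical
#'   genotype strings (e.g. `"1211"`).
#' @return An object of class `gpmap` with fields `values`, `n_loci`, `labels`.
#' @examples
#' g <- gpmap(c(0, 0.5, 1), n_loci = 1)
#' print(g)
#' @export
gpmap <- function(values, n_loci = NULL, labels = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("'values' must be non-empty")
  if (is.null(n_loci)) {
    n_loci <- round(log(length(values), base = 3))
  }
  n_loci <- as.integer(n_loci)
  if (n_loci < 1L || length(values) != 3L^n_loci) {
    stop("length(values) must be 3^n_loci (got ", length(values),
         " values for n_loci = ", n_loci, ")")
  }
  if (!all(is.finite(values))) stop("all genotypic values must be finite")
  if (is.null(labels)) {
    labels <- genotype_labels(n_loci)
  } else {
    labels <- as.character(labels)
    if (length(labels) != length(values)) {
      stop("'labels' must have one entry per genotype")
    }
  }
  structure(list(values = values, n_loci = n_loci, labels = labels),
            class = "gpmap")
}

#' @export
print.gpmap <- function(x, ...) {
  cat("GP map with", x$n_loci, "biallelic loci (",
      length(x$values), "genotypes )\n")
  df <- data.frame(genotype = x$labels, value = x$values)
  print(df, row.names = FALSE)
  invisible(x)
}

is_gpmap <- function(x) inherits(x, "gpmap")

as_gpmap <- function(x, n_loci = NULL) {
  if (is_gpmap(x)) x else gpmap(x, n_loci = n_loci)
}

#' Canonical genotype index from per-locus 2-allele counts
#'
#' The canonical (0-based) index of a genotype is
#' `sum_k c_k * 3^(N-k)` where `c_k` in `{0,1,2}` counts 2-alleles at locus
#' `k` and locus 1 is most significant. This matches the listing order
#' `1111, 1112, 1122, 1211, ..., 2222`. R vector positions are index + 1.
#'
#' @param counts integer vector of per-locus 2-allele counts (each 0, 1 or 2),
#'   or a matrix with one genotype per row.
#' @return 0-based canonical index (vector if `counts` is a matrix).
#' @seealso [genotype_counts()] for the inverse.
#' @examples
#' genotype_index(c(0, 1))  # genotype 1112 -> 1
#' @export
genotype_index <- function(counts) {
  if (is.matrix(counts)) {
    n <- ncol(counts)
    check_counts(counts)
    as.integer(counts %*% 3^((n - 1):0))
  } else {
    n <- length(counts)
    check_counts(matrix(counts, nrow = 1))
    as.integer(sum(counts * 3^((n - 1):0)))
  }
}

check_counts <- function(m) {
  if (!all(m %in% c(0, 1, 2))) {
    stop("invalid genotype: 2-allele counts must be 0, 1 or 2")
  }
  invisible(m)
}

#' Per-locus 2-allele counts from the canonical genotype index
#'
#' @param index 0-based canonical genotype index (vectorised).
#' @param n_loci number of loci.
#' @return integer matrix with one genotype per row and `n_loci` columns.
#' @export
genotype_counts <- function(index, n_loci) {
  index <- as.integer(index)
  if (any(index < 0L) || any(index >= 3L^n_loci)) {
    stop("invalid genotype index")
  }
  out <- matrix(0L, nrow = length(index), ncol = n_loci)
  rem <- index
  for (k in n_loci:1) {
    out[, k] <- rem %% 3L
    rem <- rem %/% 3L
  }
  out
}

#' All genotypes in canonical order
#'
#' @param n_loci number of loci.
#' @return `3^N x N` integer matrix of 2-allele counts, rows in canonical order.
#' @export
counts_matrix <- function(n_loci) {
  genotype_counts(0:(3L^n_loci - 1L), n_loci)
}

#' Canonical genotype labels
#'
#' @param n_loci number of loci.
#' @return character vector like `c("1111", "1112", ...)` in canonical order.
#' @export
genotype_labels <- function(n_loci) {
  cm <- counts_matrix(n_loci)
  per_locus <- c("11", "12", "22")
  apply(cm, 1, function(cc) paste(per_locus[cc + 1L], collapse = ""))
}

parse_genotype_label <- function(label, n_loci) {
  if (nchar(label) != 2L * n_loci || grepl("[^12]", label)) {
    return(NULL)
  }
  pairs <- substring(label, seq(1, 2 * n_loci, by = 2), seq(2, 2 * n_loci, by = 2))
  cc <- match(pairs, c("11", "12", "22")) - 1L
  if (anyNA(cc)) return(NULL)  # e.g. "21"
  cc
}

#' Cover relation of the genotype partial order
#'
#' The 2-allele content induces a product partial order on genotype space:
#' within every genetic background of a locus `k`, `11 < 12 < 22` at that
#' locus. The cover edges are all pairs of genotypes differing at exactly one
#' locus by one step of 2-allele content; there are `2 N 3^(N-1)` of them.
#'
#' @param n_loci number of loci.
#' @return An object of class `genotype_order`: a list with `n_loci` and
#'   `cover_edges`, a two-column integer matrix of R vector positions
#'   (canonical index + 1), column 1 the lower genotype of each edge. Edges
#'   are listed genotype-major, locus-minor, both ascending.
#' @examples
#' partial_order_covers(1)$cover_edges  # 11<12 and 12<22
#' @export
partial_order_covers <- function(n_loci) {
  n_loci <- as.integer(n_loci)
  if (n_loci < 1L) stop("n_loci must be >= 1")
  cm <- counts_matrix(n_loci)
  lo <- integer(0)
  hi <- integer(0)
  step <- as.integer(3^((n_loci - 1L):0L))
  for (g in seq_len(nrow(cm))) {
    for (k in seq_len(n_loci)) {
      if (cm[g, k] < 2L) {
        lo <- c(lo, g)
        hi <- c(hi, g + step[k])
      }
    }
  }
  structure(list(n_loci = n_loci,
                 cover_edges = cbind(lower = lo, upper = hi)),
            class = "genotype_order")
}

#' @export
print.genotype_order <- function(x, ...) {
  cat("Genotype partial order on", 3^x$n_loci, "genotypes:",
      nrow(x$cover_edges), "cover edges\n")
  invisible(x)
}
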