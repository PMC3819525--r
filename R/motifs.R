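#' Enumerate all admissible 3-gene connectivity matrices
#'
#' A regulatory wiring of three genes is a 3x3 signed connectivity matrix
#' `A` with `A[k,l]` in `{-1,0,1}` (`X_l` represses / does not regulate /
#' activates `X_k`) and at most two regulators (non-zero entries) per row,
#' the limit under which Boolean AND composition of two Hill terms applies.
#' There are `19^3 = 6859` such matrices.
#'
#' @return integer matrix with 6859 rows and 9 columns `A11, A12, ..., A33`
#'   (row-major flattening of `A`), rows in deterministic lexicographic
#'   order.
#' @export
enumerate_connectivity <- function() {
  rows <- as.matrix(expand.grid(A3 = c(-1L, 0L, 1L), A2 = c(-1L, 0L, 1L),
                                A1 = c(-1L, 0L, 1L)))[, 3:1]
  rows <- rows[rowSums(rows != 0L) <= 2L, , drop = FALSE]
  rows <- rows[do.call(order, as.data.frame(rows)), , drop = FALSE]
  idx <- as.matrix(expand.grid(r3 = seq_len(nrow(rows)),
                               r2 = seq_len(nrow(rows)),
                               r1 = seq_len(nrow(rows))))
  out <- cbind(rows[idx[, "r1"], ], rows[idx[, "r2"], ], rows[idx[, "r3"], ])
  colnames(out) <- as.vector(t(outer(1:3, 1:3, function(k, l)
    paste0("A", k, l))))
  ord <- do.call(order, as.data.frame(out))
  out[ord, , drop = FALSE]
}

#' Keep matrices with the phenotype gene downstream of both others
#'
#' The simulated phenotype is the expression of `X_3`, so `X_3` must be
#' downstream of both `X_1` and `X_2`: either both regulate `X_3` directly
#' (`A31*A32 != 0`), or one does directly and the other indirectly through
#' the first (`A31*A12 != 0` or `A32*A21 != 0`). Each clause weakly connects
#' all three genes, so connectedness is implied (asserted in the test suite
#' rather than filtered separately). 3724 matrices remain.
#'
#' @param matrices flattened connectivity matrices from
#'   [enumerate_connectivity()].
#' @return the retained rows.
#' @export
filter_downstream <- function(matrices) {
  keep <- (matrices[, "A31"] * matrices[, "A32"] != 0L) |
          (matrices[, "A31"] * matrices[, "A12"] != 0L) |
          (matrices[, "A32"] * matrices[, "A21"] != 0L)
  matrices[keep, , drop = FALSE]
}

# column permutation realising the X1 <-> X2 relabelling on the flattening
swap12_perm <- c("A22", "A21", "A23", "A12", "A11", "A13", "A32", "A31", "A33")

#' Reduce by the X1/X2 relabelling symmetry
#'
#' `X_1` and `X_2` play exchangeable roles upstream of the phenotype gene,
#' so matrices related by simultaneously swapping row and column indices 1
#' and 2 describe the same system. One canonical representative is kept per
#' orbit: the lexicographically smaller of the matrix and its swap
#' (row-major flattening, order `-1 < 0 < 1`); swap-invariant matrices are
#' kept once. From the 3724 downstream-filtered matrices, 1881
#' representatives remain.
#'
#' @param matrices flattened connectivity matrices.
#' @return the canonical representatives, in enumeration order.
#' @export
reduce_symmetry <- function(matrices) {
  swapped <- matrices[, swap12_perm, drop = FALSE]
  colnames(swapped) <- colnames(matrices)
  # fixed-width string keys make elementwise lexicographic comparison easy
  enc <- function(m) apply(matrix(c("a", "b", "c")[m + 2L], nrow = nrow(m)),
                           1, paste, collapse = "")
  k_orig <- enc(matrices)
  k_swap <- enc(swapped)
  use_swap <- k_swap < k_orig
  canonical <- matrices
  canonical[use_swap, ] <- swapped[use_swap, , drop = FALSE]
  canonical[!duplicated(pmin(k_orig, k_swap)), , drop = FALSE]
}

#' Feedback and feedforward loop products of a connectivity matrix
#'
#' Loop products summarise the signed cycle and feedforward structure:
#' autoregulation `FL1 = A11`, `FL2 = A22`, `FL3 = A33`; two-gene loops
#' `FL12 = A21*A12`, `FL13 = A31*A13`, `FL23 = A23*A32`; three-gene loops
#' `FL123 = A32*A21*A13`, `FL213 = A31*A12*A23`; feedforward products
#' `FFL32 = A32*(A31*A12)` and `FFL31 = A31*(A32*A21)`. A non-zero product
#' indicates the loop is present; its sign is the sign of the loop. A
#' negative feedforward product marks an incoherent feedforward (the direct
#' and indirect paths to `X_3` have opposite net signs).
#'
#' @param A a 3x3 connectivity matrix, a flattened length-9 vector, or a
#'   many-row flattened matrix.
#' @return data frame with columns `FL1, FL2, FL3, FL12, FL13, FL23, FL123,
#'   FL213, FFL32, FFL31`, one row per input matrix.
#' @export
loop_products <- function(A) {
  m <- flatten_connectivity(A)
  data.frame(
    FL1   = m[, "A11"], FL2 = m[, "A22"], FL3 = m[, "A33"],
    FL12  = m[, "A21"] * m[, "A12"],
    FL13  = m[, "A31"] * m[, "A13"],
    FL23  = m[, "A23"] * m[, "A32"],
    FL123 = m[, "A32"] * m[, "A21"] * m[, "A13"],
    FL213 = m[, "A31"] * m[, "A12"] * m[, "A23"],
    FFL32 = m[, "A32"] * m[, "A31"] * m[, "A12"],
    FFL31 = m[, "A31"] * m[, "A32"] * m[, "A21"])
}

flatten_connectivity <- function(A) {
  nm <- as.vector(t(outer(1:3, 1:3, function(k, l) paste0("A", k, l))))
  if (is.matrix(A) && nrow(A) == 3L && ncol(A) == 3L) {
    m <- matrix(as.integer(t(A)), nrow = 1)
  } else if (is.matrix(A) && ncol(A) == 9L) {
    m <- A
  } else if (is.numeric(A) && length(A) == 9L) {
    m <- matrix(as.integer(A), nrow = 1)
  } else {
    stop("'A' must be a 3x3 matrix or a row-major flattening")
  }
  if (!all(m %in% c(-1L, 0L, 1L))) stop("connectivity entries must be -1, 0 or 1")
  colnames(m) <- nm
  m
}

unflatten_connectivity <- function(flat) {
  matrix(as.integer(flat), nrow = 3, byrow = TRUE,
         dimnames = list(paste0("X", 1:3), paste0("X", 1:3)))
}

#' Classify a motif by incoherent feedforward and positive feedback content
#'
#' A motif contains an incoherent feedforward when `FFL32 < 0` or
#' `FFL31 < 0`, and a positive feedback loop when any of the eight feedback
#' loop products (autoregulation included) is positive. These two booleans
#' partition the motif space into four classes, the architecture features
#' that predispose a network for non-monotone GP maps.
#'
#' @inheritParams loop_products
#' @return data frame with `has_incoherent_ffl`, `has_positive_fb` and
#'   `class` (one of `"both"`, `"incoherent_ffl_only"`, `"positive_fb_only"`,
#'   `"neither"`), one row per matrix.
#' @export
classify_motif <- function(A) {
  lp <- loop_products(A)
  fl <- as.matrix(lp[, c("FL1", "FL2", "FL3", "FL12", "FL13", "FL23",
                         "FL123", "FL213")])
  incoh <- lp$FFL32 < 0L | lp$FFL31 < 0L
  posfb <- rowSums(fl > 0L) > 0L
  cls <- ifelse(incoh & posfb, "both",
         ifelse(incoh, "incoherent_ffl_only",
         ifelse(posfb, "positive_fb_only", "neither")))
  data.frame(has_incoherent_ffl = incoh, has_positive_fb = posfb,
             class = cls, stringsAsFactors = FALSE)
}

#' Full motif table: representatives, loop products and classes
#'
#' Runs the enumeration pipeline (enumerate 6859, downstream-filter to 3724,
#' symmetry-reduce to 1881) and annotates each representative with its loop
#' products and 4-way class.
#'
#' @return data frame with `motif_id`, the nine flattened entries of `A`,
#'   the ten loop products and the classification columns.
#' @export
motif_table <- function() {
  reps <- reduce_symmetry(filter_downstream(enumerate_connectivity()))
  cbind(data.frame(motif_id = seq_len(nrow(reps))),
        as.data.frame(reps),
        loop_products(reps),
        classify_motif(reps))
}
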