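# Independent oracles used across the suite.

# Generic constrained quadratic solver route for the isotonic projection:
# min ||h - v||^2 (weighted) subject to h[lo] <= h[hi] for all cover edges.
oracle_isotonic_qp <- function(values, n_loci, weights = NULL) {
  edges <- partial_order_covers(n_loci)$cover_edges
  n <- length(values)
  if (is.null(weights)) weights <- rep(1, n)
  Amat <- matrix(0, nrow = n, ncol = nrow(edges))
  for (e in seq_len(nrow(edges))) {
    Amat[edges[e, 1], e] <- -1  # h[hi] - h[lo] >= 0
    Amat[edges[e, 2], e] <- 1
  }
  sol <- quadprog::solve.QP(Dmat = diag(weights), dvec = weights * values,
                            Amat = Amat, bvec = rep(0, nrow(edges)))
  sol$solution
}

# Brute-force order-preservation check straight from the defining
# inequalities: for every background of every locus, values non-decreasing
# along 11 -> 12 -> 22 under one of the two allele labellings of that locus
# (i.e. all steps >= 0 or all steps <= 0, beyond tolerance).
brute_monotone_loci <- function(g, zero_tol = 0) {
  cm <- counts_matrix(g$n_loci)
  vapply(seq_len(g$n_loci), function(k) {
    up <- TRUE; down <- TRUE
    for (row in seq_len(nrow(cm))) {
      cc <- cm[row, ]
      if (cc[k] < 2) {
        cc2 <- cc; cc2[k] <- cc[k] + 1L
        step <- g$values[genotype_index(cc2) + 1L] -
                g$values[genotype_index(cc) + 1L]
        if (step < -zero_tol) up <- FALSE
        if (step > zero_tol) down <- FALSE
      }
    }
    up || down
  }, TRUE)
}

# Weighted least-squares objective of a candidate isotonic fit.
iso_objective <- function(values, fit, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(values))
  sum(weights * (values - fit)^2)
}

# Reachability in the cover-edge DAG (for transitive-closure checks).
reachable <- function(edges, from, n) {
  seen <- logical(n)
  frontier <- from
  seen[from] <- TRUE
  while (length(frontier)) {
    nxt <- edges[edges[, 1] %in% frontier, 2]
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

mouseweight_values <- c(31.23, 34.13, 33.82, 34.89, 35.90, 36.53,
                        34.12, 37.95, 36.84)
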