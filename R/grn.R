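#' Sigmoid (Hill) gene regulation function
#'
#' Dose-response `S(y, theta, p) = y^p / (y^p + theta^p)` for an activator,
#' and `1 - S` for a repressor. `theta` is the regulator concentration giving
#' half-maximal production and `p` the steepness of the response.
#'
#' @param y regulator concentration (non-negative, vectorised).
#' @param theta half-maximal concentration (positive).
#' @param p steepness (positive, dimensionless).
#' @param mode `"activator"` or `"repressor"`.
#' @return response in `[0, 1]`.
#' @examples
#' hill(30, 30, 4)  # 0.5 at the threshold, any steepness
#' @export
hill <- function(y, theta, p, mode = c("activator", "repressor")) {
  mode <- match.arg(mode)
  if (any(y < 0) || any(theta <= 0) || any(p <= 0)) {
    stop("hill() requires y >= 0, theta > 0, p > 0")
  }
  # compute on the ratio to avoid overflow for large y^p
  r <- (y / theta)^p
  s <- ifelse(is.infinite(r), 1, r / (r + 1))
  if (mode == "activator") s else 1 - s
}

#' Allele-level gene regulation function under Boolean AND
#'
#' The production-rate multiplier `R_ki` for allele `i` of gene `k`: 1 when
#' the gene has no regulators (production always switched on), a single Hill
#' term for one regulator (activating or repressing per the sign of
#' `A[k,l]`), and the product of the two Hill terms (Boolean AND) for two
#' regulators.
#'
#' @param A 3x3 connectivity matrix.
#' @param gene gene index `k` in 1..3.
#' @param y numeric vector of the three total expression levels.
#' @param theta,p length-3 vectors of allele-specific regulation parameters
#'   indexed by regulator (entries for non-regulators are ignored).
#' @return multiplier in `[0, 1]`.
#' @export
regulation_function <- function(A, gene, y, theta, p) {
  regs <- which(A[gene, ] != 0L)
  if (length(regs) > 2L) stop("at most 2 regulators per gene")
  R <- 1
  for (l in regs) {
    mode <- if (A[gene, l] > 0L) "activator" else "repressor"
    R <- R * hill(y[l], theta[l], p[l], mode)
  }
  R
}

#' Right-hand side of the diploid sigmoid network ODE
#'
#' Six state variables `x[k,i]` track the expression of the two alleles
#' (`i = 1, 2`) of each gene (`k = 1, 2, 3`). Each allele is produced at its
#' own maximal rate times its own regulation function evaluated at the gene
#' totals `y_k = x[k,1] + x[k,2]`, and decays linearly:
#' `dx[k,i]/dt = alpha[k,i] * R_ki(y1, y2, y3) - gamma[k,i] * x[k,i]`.
#'
#' @param state numeric length-6 state, ordered `x11, x12, x21, x22, x31,
#'   x32` (gene-major, allele slot minor).
#' @param gp genotype parameter set from [genotype_parameters()].
#' @return numeric length-6 derivative.
#' @export
grn_rhs <- function(state, gp) {
  if (length(state) != 6L) stop("state must have 6 components")
  x <- matrix(state, nrow = 3, byrow = TRUE)
  y <- rowSums(x)
  dx <- x
  for (k in 1:3) {
    for (j in 1:2) {
      R <- regulation_function(gp$A, k, y, gp$theta[, k, j], gp$p[, k, j])
      dx[k, j] <- gp$alpha[k, j] * R - gp$gamma * x[k, j]
    }
  }
  as.numeric(t(dx))
}

#' Simulation configuration for the network study
#'
#' @param pleiotropy if `TRUE`, allelic variation enters the maximal
#'   production rate, the regulation thresholds and steepnesses together;
#'   if `FALSE`, only the production rate (thresholds/steepnesses shared by
#'   both alleles of a gene).
#' @param n_reps Monte Carlo replicates per motif.
#' @param seed root seed for the study.
#' @param abs_flat,rel_flat flatness thresholds: a map is usable only when
#'   its absolute range (max - min) and relative range (range / mean) both
#'   exceed these.
#' @param conv_tol relative convergence tolerance for the windowed
#'   integration.
#' @param t_window,t_max integration window length and time cap (the decay
#'   rate 10 sets an intrinsic time constant of 0.1).
#' @param min_usable_frac per-1000-replicate usable-map threshold for
#'   motif-level inclusion (scaled proportionally when `n_reps` differs from
#'   1000).
#' @return list of settings (class `grn_config`).
#' @export
grn_config <- function(pleiotropy = FALSE, n_reps = 1000L, seed = 1L,
                       abs_flat = 0.01, rel_flat = 0.01,
                       conv_tol = 1e-6, t_window = 10, t_max = 1000,
                       min_usable_frac = 100 / 1000) {
  stopifnot(n_reps >= 1, abs_flat > 0, rel_flat > 0, conv_tol > 0,
            t_window > 0, t_max >= t_window)
  structure(list(pleiotropy = isTRUE(pleiotropy), n_reps = as.integer(n_reps),
                 seed = as.integer(seed), abs_flat = abs_flat,
                 rel_flat = rel_flat, conv_tol = conv_tol,
                 t_window = t_window, t_max = t_max,
                 min_usable = ceiling(min_usable_frac * n_reps)),
            class = "grn_config")
}

#' Sample allelic network parameters for one Monte Carlo replicate
#'
#' Draws the allele-level parameters of the diploid network: maximal
#' production rates `alpha ~ U(100, 200)` per gene and allele; regulation
#' thresholds `theta ~ U(20, 40)` and steepnesses `p ~ U(1, 10)` per
#' gene-regulator pair. All decay rates are fixed at 10. Without pleiotropy
#' the two allelic variants of a gene share the same `theta` and `p` (drawn
#' once per gene-regulator pair) and differ only in `alpha`; with pleiotropy
#' each allelic variant carries its own `theta` and `p` as well. Uses the
#' current RNG state.
#'
#' @param A 3x3 connectivity matrix.
#' @param pleiotropy logical.
#' @return list (class `grn_params`) with `A`, `alpha` (3x2: gene x allelic
#'   variant), `theta` and `p` (3x3x2: regulator x gene x variant; `NA` for
#'   absent edges) and `gamma = 10`.
#' @export
sample_genotype_parameters <- function(A, pleiotropy = FALSE) {
  A <- unflatten_connectivity(flatten_connectivity(A))
  alpha <- matrix(stats::runif(6, 100, 200), nrow = 3, ncol = 2)
  theta <- array(NA_real_, dim = c(3, 3, 2))
  p <- array(NA_real_, dim = c(3, 3, 2))
  for (k in 1:3) {
    for (l in which(A[k, ] != 0L)) {
      if (pleiotropy) {
        theta[l, k, ] <- stats::runif(2, 20, 40)
        p[l, k, ] <- stats::runif(2, 1, 10)
      } else {
        theta[l, k, ] <- stats::runif(1, 20, 40)
        p[l, k, ] <- stats::runif(1, 1, 10)
      }
    }
  }
  structure(list(A = A, alpha = alpha, theta = theta, p = p, gamma = 10),
            class = "grn_params")
}

#' Assemble the parameter set of one diploid genotype
#'
#' Maps a genotype (per-locus 2-allele counts) onto the six allele slots of
#' the ODE system: a homozygote duplicates one allelic variant's parameters
#' in both slots, a heterozygote combines variant 1 and variant 2.
#'
#' @param params a `grn_params` set from [sample_genotype_parameters()].
#' @param counts integer length-3 vector of 2-allele counts.
#' @return list with `A`, slot-level `alpha` (3x2), `theta`, `p` (3x3x2 by
#'   slot) and `gamma`.
#' @export
genotype_parameters <- function(params, counts) {
  check_counts(matrix(counts, nrow = 1))
  if (length(counts) != 3L) stop("counts must have length 3")
  variant <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 2L))[counts + 1L, , drop = FALSE]
  alpha <- params$alpha
  theta <- params$theta
  p <- params$p
  out_alpha <- matrix(0, 3, 2)
  out_theta <- array(NA_real_, dim = c(3, 3, 2))
  out_p <- array(NA_real_, dim = c(3, 3, 2))
  for (k in 1:3) {
    for (j in 1:2) {
      v <- variant[k, j]
      out_alpha[k, j] <- alpha[k, v]
      out_theta[, k, j] <- theta[, k, v]
      out_p[, k, j] <- p[, k, v]
    }
  }
  list(A = params$A, alpha = out_alpha, theta = out_theta, p = out_p,
       gamma = params$gamma)
}

# Flatten a genotype parameter set into edge arrays for a fast RHS. Slots
# are numbered s = 2(k-1)+j for gene k, allele slot j, matching the state
# ordering x11, x12, x21, x22, x31, x32.
compile_genotype <- function(gp) {
  slot <- integer(0); reg <- integer(0); repress <- logical(0)
  theta <- numeric(0); p <- numeric(0)
  for (k in 1:3) {
    for (l in which(gp$A[k, ] != 0L)) {
      for (j in 1:2) {
        slot <- c(slot, 2L * (k - 1L) + j)
        reg <- c(reg, l)
        repress <- c(repress, gp$A[k, l] < 0L)
        theta <- c(theta, gp$theta[l, k, j])
        p <- c(p, gp$p[l, k, j])
      }
    }
  }
  list(alpha = as.numeric(t(gp$alpha)), gamma = gp$gamma,
       slot = slot, reg = reg, repress = repress, theta = theta, p = p)
}

rhs_fast <- function(state, pc) {
  y <- pmax(state[c(1, 3, 5)] + state[c(2, 4, 6)], 0)
  R <- rep(1, 6)
  if (length(pc$slot)) {
    r <- (y[pc$reg] / pc$theta)^pc$p
    s <- r / (r + 1)
    s[is.infinite(r)] <- 1
    s[pc$repress] <- 1 - s[pc$repress]
    for (e in seq_along(pc$slot)) R[pc$slot[e]] <- R[pc$slot[e]] * s[e]
  }
  pc$alpha * R - pc$gamma * state
}

#' Steady state of the diploid network for one genotype
#'
#' Integrates the ODE system from the all-zero state in windows of
#' `t_window` time units until the state stops changing (maximal relative
#' change per window and residual both below `conv_tol`), then polishes the
#' equilibrium with Newton iteration on the algebraic system and verifies
#' local stability (all Jacobian eigenvalues with negative real part).
#' Anything else -- the time cap reached without settling (including
#' sustained oscillation), Newton failure, or an unstable/non-hyperbolic
#' point -- is reported as non-convergence, never as an error.
#'
#' @param gp genotype parameter set from [genotype_parameters()].
#' @param config a [grn_config()].
#' @return list with `converged` (logical), `state` (length 6), `y` (three
#'   gene totals), `phenotype` (equilibrium `y3`) and `reason` (`"ok"` or
#'   `"non_convergence"`).
#' @export
steady_state <- function(gp, config = grn_config()) {
  pc <- compile_genotype(gp)
  f <- function(t, state, parms) list(rhs_fast(state, pc))
  state <- rep(0, 6)
  t <- 0
  settled <- FALSE
  while (t < config$t_max) {
    sol <- tryCatch(
      suppressWarnings(
        deSolve::lsoda(y = state, times = c(0, config$t_window), func = f,
                       rtol = 1e-6, atol = 1e-6)),
      error = function(e) NULL)
    if (is.null(sol) || nrow(sol) < 2L || any(!is.finite(sol[2, -1]))) {
      return(nonconverged())
    }
    new_state <- as.numeric(sol[2, -1])
    t <- t + config$t_window
    scale <- max(abs(new_state), 1)
    if (max(abs(new_state - state)) / scale < config$conv_tol &&
        max(abs(rhs_fast(new_state, pc))) < config$conv_tol * scale) {
      state <- new_state
      settled <- TRUE
      break
    }
    state <- new_state
  }
  if (!settled) return(nonconverged())
  polished <- newton_polish(state, pc)
  if (is.null(polished)) return(nonconverged())
  x <- matrix(polished, nrow = 3, byrow = TRUE)
  y <- rowSums(x)
  list(converged = TRUE, state = polished, y = y, phenotype = y[3],
       reason = "ok")
}

nonconverged <- function() {
  list(converged = FALSE, state = NULL, y = NULL, phenotype = NA_real_,
       reason = "non_convergence")
}

# Newton refinement of an equilibrium located by integration; returns NULL
# unless Newton converges to a strictly stable point.
newton_polish <- function(state, pc, max_iter = 50L) {
  x <- state
  for (iter in seq_len(max_iter)) {
    fx <- rhs_fast(x, pc)
    J <- num_jacobian(x, pc)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    x <- pmax(x + step, 0)
    if (max(abs(rhs_fast(x, pc))) < 1e-12 * max(abs(x), 1)) break
    if (iter == max_iter) return(NULL)
  }
  J <- num_jacobian(x, pc)
  ev <- eigen(J, only.values = TRUE)$values
  if (max(Re(ev)) >= -1e-8) return(NULL)
  x
}

num_jacobian <- function(x, pc, h = NULL) {
  n <- length(x)
  if (is.null(h)) h <- 1e-6 * pmax(abs(x), 1)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    xp <- x; xp[j] <- x[j] + h[j]
    xm <- x; xm[j] <- max(x[j] - h[j], 0)
    J[, j] <- (rhs_fast(xp, pc) - rhs_fast(xm, pc)) / (xp[j] - xm[j])
  }
  J
}

#' Simulate the GP map of one network parameterisation
#'
#' Solves the diploid network to steady state for each of the 27 three-locus
#' genotypes (heterozygotes combine the two allelic parameter variants,
#' homozygotes duplicate one) and records the equilibrium `y_3` as the
#' genotypic value. The replicate is discarded when any genotype fails to
#' converge, or when the resulting map is essentially flat (absolute range
#' `<= abs_flat` or relative range `<= rel_flat`), since such maps are
#' dominated by solver tolerance.
#'
#' @param params a `grn_params` set from [sample_genotype_parameters()].
#' @param config a [grn_config()].
#' @return list with `ok` (logical), `gpmap` (a 3-locus [gpmap] or `NULL`)
#'   and `reason` (`"ok"`, `"non_convergence"` or `"flat"`).
#' @export
simulate_gpmap <- function(params, config = grn_config()) {
  cm <- counts_matrix(3L)
  values <- numeric(nrow(cm))
  for (gidx in seq_len(nrow(cm))) {
    gp <- genotype_parameters(params, cm[gidx, ])
    ss <- steady_state(gp, config)
    if (!ss$converged) {
      return(list(ok = FALSE, gpmap = NULL, reason = "non_convergence"))
    }
    values[gidx] <- ss$phenotype
  }
  rng <- max(values) - min(values)
  rel <- rng / mean(values)
  if (!(rng > config$abs_flat && rel > config$rel_flat)) {
    return(list(ok = FALSE, gpmap = NULL, reason = "flat"))
  }
  list(ok = TRUE, gpmap = gpmap(values, n_loci = 3), reason = "ok")
}
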