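#' Monte Carlo study of GP maps across network motifs
#'
#' For each motif, repeatedly samples allelic network parameters, simulates
#' the 27-genotype GP map, and summarises the usable maps: order-breaking
#' locus counts, the substitution-effect degree of monotonicity `m`, the
#' isotonic `R2_mono` and the additive variance ratio `V_A/V_G`. Replicates
#' that fail to converge or give essentially flat maps are discarded and
#' counted by reason. Motifs whose usable count falls below the (scaled)
#' inclusion threshold are flagged rather than dropped.
#'
#' Randomness flows from one root seed: each motif gets its own
#' deterministic stream (derived from the root seed and the motif id), and
#' replicates draw sequentially within it, so any subset of motifs
#' reproduces exactly.
#'
#' @param motifs a data frame from [motif_table()] (or a subset of it), or a
#'   list of 3x3 connectivity matrices.
#' @param config a [grn_config()].
#' @param keep_maps keep the usable [gpmap]s (list column `maps`)?
#' @param measures compute `m`/`R2_mono`/`V_A/V_G` per usable map (disable
#'   for timing-only runs).
#' @return object of class `grn_mc`: list with `summary` data frame (one
#'   row per motif: id, flattened `A`, class, replicate accounting, the
#'   order-breaking histogram `ob0..ob3`, and mean/quantile summaries of the
#'   three measures), `config`, and optionally `maps`.
#' @export
monte_carlo_study <- function(motifs, config = grn_config(),
                              keep_maps = FALSE, measures = TRUE) {
  motifs <- normalise_motifs(motifs)
  n_motif <- nrow(motifs)
  rows <- vector("list", n_motif)
  all_maps <- if (keep_maps) vector("list", n_motif) else NULL
  for (i in seq_len(n_motif)) {
    A <- unflatten_connectivity(as.integer(motifs[i, a_cols()]))
    set.seed(motif_stream_seed(config$seed, motifs$motif_id[i]))
    n_ok <- 0L; n_nc <- 0L; n_flat <- 0L
    ob <- integer(4)  # order-breaking w.r.t. 0..3 loci
    m_vals <- r2_vals <- va_vals <- numeric(0)
    maps <- list()
    for (r in seq_len(config$n_reps)) {
      params <- sample_genotype_parameters(A, pleiotropy = config$pleiotropy)
      sim <- simulate_gpmap(params, config)
      if (!sim$ok) {
        if (sim$reason == "flat") n_flat <- n_flat + 1L else n_nc <- n_nc + 1L
        next
      }
      n_ok <- n_ok + 1L
      if (measures) {
        rep_mono <- degree_of_monotonicity(sim$gpmap)
        ob[rep_mono$order_breaking_count + 1L] <-
          ob[rep_mono$order_breaking_count + 1L] + 1L
        m_vals <- c(m_vals, rep_mono$m)
        r2_vals <- c(r2_vals, decompose_monotone(sim$gpmap)$r2_mono)
        va_vals <- c(va_vals, variance_components(sim$gpmap)$ratio)
      }
      if (keep_maps) maps[[length(maps) + 1L]] <- sim$gpmap
    }
    q <- function(x, p) if (length(x)) as.numeric(stats::quantile(x, p)) else NA_real_
    rows[[i]] <- data.frame(
      motif_id = motifs$motif_id[i],
      motifs[i, a_cols(), drop = FALSE],
      class = motifs$class[i],
      n_reps = config$n_reps, usable = n_ok,
      discarded_nonconvergence = n_nc, discarded_flat = n_flat,
      included = n_ok >= config$min_usable,
      ob0 = ob[1], ob1 = ob[2], ob2 = ob[3], ob3 = ob[4],
      mean_m = if (length(m_vals)) mean(m_vals) else NA_real_,
      min_m = if (length(m_vals)) min(m_vals) else NA_real_,
      r2_mono_q25 = q(r2_vals, 0.25), r2_mono_q50 = q(r2_vals, 0.5),
      va_vg_q25 = q(va_vals, 0.25), va_vg_q50 = q(va_vals, 0.5),
      row.names = NULL)
    if (keep_maps) all_maps[[i]] <- maps
  }
  out <- list(summary = do.call(rbind, rows), config = config)
  if (keep_maps) out$maps <- all_maps
  structure(out, class = "grn_mc")
}

a_cols <- function() as.vector(t(outer(1:3, 1:3, function(k, l)
  paste0("A", k, l))))

# deterministic per-motif stream seed below 2^31
motif_stream_seed <- function(root_seed, motif_id) {
  as.integer((as.numeric(root_seed) * 48271 + as.numeric(motif_id) * 16807) %%
               2147483647)
}

normalise_motifs <- function(motifs) {
  if (is.data.frame(motifs)) {
    if (!all(a_cols() %in% names(motifs))) {
      stop("motif data frame must contain columns ", paste(a_cols(), collapse = ", "))
    }
    if (is.null(motifs$motif_id)) motifs$motif_id <- seq_len(nrow(motifs))
    if (is.null(motifs$class)) {
      motifs$class <- classify_motif(as.matrix(motifs[, a_cols()]))$class
    }
    motifs
  } else {
    if (is.matrix(motifs)) motifs <- list(motifs)
    flat <- do.call(rbind, lapply(motifs, flatten_connectivity))
    df <- as.data.frame(flat)
    df$motif_id <- seq_len(nrow(df))
    df$class <- classify_motif(flat)$class
    df
  }
}

#' @export
print.grn_mc <- function(x, ...) {
  s <- x$summary
  cat("Monte Carlo network study:", nrow(s), "motifs x", x$config$n_reps,
      "replicates (pleiotropy:", x$config$pleiotropy, ")\n")
  cat("  usable maps:", sum(s$usable),
      "| discarded:", sum(s$discarded_nonconvergence), "non-convergent,",
      sum(s$discarded_flat), "flat\n")
  cat("  motifs meeting the inclusion threshold (>=", x$config$min_usable,
      "usable):", sum(s$included), "\n")
  invisible(x)
}
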