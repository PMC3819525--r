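#' Read a GP map from CSV or JSON
#'
#' CSV files carry a mandatory `genotype,value` header and one row per
#' genotype, genotype strings of `2N` characters from `{1,2}` (e.g.
#' `"1211"`); rows may appear in any order but must cover every genotype
#' exactly once. JSON files carry `{"n_loci": N, "values": [...]}` with
#' values in canonical order.
#'
#' @param path file path; format chosen by extension (`.json` vs anything
#'   else as CSV).
#' @return a [gpmap] with values in canonical order.
#' @export
read_gpmap <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$n_loci) || is.null(obj$values)) {
      stop("JSON GP map must contain 'n_loci' and 'values'")
    }
    return(gpmap(as.numeric(obj$values), n_loci = obj$n_loci))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character"))
  if (!all(c("genotype", "value") %in% names(df))) {
    stop("GP map CSV must have header 'genotype,value'")
  }
  n_geno <- nrow(df)
  n_loci <- round(log(n_geno, base = 3))
  if (3^n_loci != n_geno) {
    stop("GP map CSV must have 3^N rows; got ", n_geno)
  }
  values <- numeric(n_geno)
  seen <- logical(n_geno)
  for (r in seq_len(n_geno)) {
    cc <- parse_genotype_label(df$genotype[r], n_loci)
    if (is.null(cc)) {
      stop("row ", r, ": malformed genotype '", df$genotype[r], "'")
    }
    idx <- genotype_index(cc) + 1L
    if (seen[idx]) stop("duplicate genotype '", df$genotype[r], "'")
    v <- suppressWarnings(as.numeric(df$value[r]))
    if (is.na(v)) stop("row ", r, ": non-numeric value '", df$value[r], "'")
    values[idx] <- v
    seen[idx] <- TRUE
  }
  if (!all(seen)) {
    stop("missing genotype '", genotype_labels(n_loci)[which(!seen)[1]], "'")
  }
  gpmap(values, n_loci = n_loci)
}

#' Write a GP map to CSV or JSON
#'
#' @param gpmap a [gpmap].
#' @param path output path; `.json` writes the JSON form, anything else the
#'   canonical-order CSV.
#' @param digits significant digits for CSV output (12 by default so
#'   repeated runs are byte-identical on one platform).
#' @return `path`, invisibly.
#' @export
write_gpmap <- function(gpmap, path, digits = 12) {
  g <- as_gpmap(gpmap)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(n_loci = g$n_loci, values = g$values), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(genotype = genotype_labels(g$n_loci),
                     value = signif(g$values, digits))
    utils::write.csv(format(df, scientific = FALSE, trim = TRUE), path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
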