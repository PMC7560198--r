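#' Filter proteins by replicate presence
#'
#' Retains proteins with at least `min_detected` genuine (pre-imputation)
#' measurements in at least one group (`scope = "any_group"`) or in one named
#' group (`scope = "per_group"`, with `group`). This is the workflow's
#' consistency filter: with defaults, a protein must be quantified in 5 of 6
#' biological replicates of at least one cell type to enter the resource.
#'
#' @param table an [intensity_table()]
#' @param min_detected minimum replicates with a measured value
#' @param scope `"any_group"` or `"per_group"`
#' @param group group name, required when `scope = "per_group"`
#' @return the filtered [intensity_table()], row order preserved; a
#'   `report` attribute carries kept/removed counts
#' @export
filter_by_replication <- function(table, min_detected = 5L,
                                  scope = c("any_group", "per_group"),
                                  group = NULL) {
  scope <- match.arg(scope)
  counts <- detection_counts(table)
  if (scope == "per_group") {
    if (is.null(group) || !group %in% colnames(counts$counts))
      stop("unknown group: ", if (is.null(group)) "<missing>" else group)
    keep <- counts$counts[, group] >= min_detected
  } else {
    keep <- apply(counts$counts >= min_detected, 1L, any)
  }
  if (any(min_detected > counts$totals))
    stop("min_detected exceeds the replicate count of group(s): ",
         paste(names(counts$totals)[min_detected > counts$totals], collapse = ", "))
  out <- subset_proteins(table, keep)
  attr(out, "report") <- list(kept = sum(keep), removed = sum(!keep))
  out
}

#' Log-transform a raw intensity table
#'
#' @param table a raw-scale [intensity_table()]
#' @param base 2 or 10
#' @return the table on `log2` or `log10` scale; missing values untouched
#' @export
log_transform <- function(table, base = 2) {
  if (table$scale != "raw") stop("log_transform requires a raw-scale table")
  if (!base %in% c(2, 10)) stop("base must be 2 or 10")
  if (any(table$values <= 0, na.rm = TRUE))
    stop("non-positive intensity encountered; raw tables must be strictly positive")
  vals <- log(table$values, base = base)
  intensity_table(vals, table$design, scale = if (base == 2) "log2" else "log10",
                  detected = table$detected, imputed = table$imputed)
}

#' Back-transform a log-scale table to raw intensities
#' @param table a log2- or log10-scale [intensity_table()]
#' @return a raw-scale [intensity_table()]
#' @export
unlog_transform <- function(table) {
  base <- switch(table$scale, log2 = 2, log10 = 10,
                 stop("table is not on a log scale"))
  intensity_table(base ^ table$values, table$design, scale = "raw",
                  detected = table$detected, imputed = table$imputed)
}

#' Impute missing values from a left-shifted Gaussian
#'
#' Missing-value imputation for left-censored (missing-not-at-random) LFQ
#' data: for each sample column with observed mean `m` and standard
#' deviation `s` (present values only), each missing entry is replaced by an
#' independent draw from Normal(`m - shift*s`, `(width*s)^2`). Defaults
#' (shift 1.8 SD, width 0.3 SD) are the Perseus-style down-shift the
#' workflow uses. Imputed cells are flagged in the `imputed` matrix and the
#' pre-imputation `detected` mask is preserved, so downstream detection
#' counts are unaffected. Column statistics for all columns are computed
#' before any filling, and columns are filled left to right, so results are
#' reproducible from the seed.
#'
#' @param table a log2-scale [intensity_table()]
#' @param shift down-shift in column-SD units (default 1.8)
#' @param width width in column-SD units (default 0.3)
#' @param seed integer seed
#' @return the imputed [intensity_table()]
#' @export
impute_left_shifted <- function(table, shift = 1.8, width = 0.3, seed = 1L) {
  if (table$scale != "log2")
    stop("impute_left_shifted requires a log2-scale table")
  vals <- table$values
  n_present <- colSums(!is.na(vals))
  if (any(n_present < 2L))
    stop("column(s) with fewer than 2 present values: ",
         paste(colnames(vals)[n_present < 2L], collapse = ", "),
         "; filter more strictly before imputing")
  m <- colMeans(vals, na.rm = TRUE)
  s <- apply(vals, 2L, stats::sd, na.rm = TRUE)
  imputed <- table$imputed
  withr::local_seed(seed)
  for (j in seq_len(ncol(vals))) {
    miss <- which(is.na(vals[, j]))
    if (!length(miss)) next
    vals[miss, j] <- stats::rnorm(length(miss), mean = m[j] - shift * s[j],
                                  sd = width * s[j])
    imputed[miss, j] <- TRUE
  }
  intensity_table(vals, table$design, scale = "log2",
                  detected = table$detected, imputed = imputed)
}
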