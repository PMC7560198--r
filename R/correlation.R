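#' Pairwise Pearson correlation between samples
#'
#' Reproducibility diagnostic: Pearson correlation coefficients between all
#' sample columns of a log-scale table. With `use = "pairwise"` each pair is
#' computed on its shared present values (entries with fewer than 3 shared
#' values are set to `NA` with a warning); with `use = "complete"` the table
#' is expected to be imputed and all rows are used.
#'
#' @param table a log-scale [intensity_table()]
#' @param use `"pairwise"` or `"complete"`
#' @return a symmetric correlation matrix with unit diagonal, sample ids as
#'   dimnames, class `correlation_matrix`
#' @export
pearson_matrix <- function(table, use = c("pairwise", "complete")) {
  use <- match.arg(use)
  if (table$scale == "raw")
    stop("pearson_matrix expects a log-scale table")
  vals <- table$values
  if (use == "complete" && anyNA(vals))
    stop("use = 'complete' requires an imputed (complete) table")
  cm <- stats::cor(vals, use = if (use == "pairwise") "pairwise.complete.obs" else "everything",
                   method = "pearson")
  present <- !is.na(vals)
  shared <- crossprod(present)          # pairwise count of shared present values
  few <- shared < 3L
  diag(few) <- FALSE
  if (any(few)) {
    warning(sum(few) / 2L, " sample pair(s) share fewer than 3 values; set to NA")
    cm[few] <- NA_real_
  }
  diag(cm) <- 1
  cm <- (cm + t(cm)) / 2               # enforce exact symmetry
  class(cm) <- c("correlation_matrix", class(cm))
  cm
}
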