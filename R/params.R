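#' Analysis parameter set
#'
#' Bundles every tunable threshold of the pipeline so the workflow constants
#' live in one place. Defaults follow the published secretome workflow:
#' proteins must be quantified in at least `min_detected` of `n_replicates`
#' biological replicates; missing values are imputed from a Gaussian shifted
#' down by 1.8 column standard deviations with width 0.3; cell-type-specific
#' secretion requires a fivefold pairwise enrichment (or near-exclusive
#' detection); lysate specificity uses 2.5-fold; differential abundance
#' requires Bonferroni p < `alpha` and |log2 fold change| >= `da_log2fc_min`;
#' the SAM-style volcano test uses fudge constant `s0`; disease associations
#' are kept at evidence index >= `ei_min`.
#'
#' @param min_detected minimum replicates with a measured value (default 5)
#' @param n_replicates replicates per group the design is expected to carry (default 6)
#' @param impute_shift down-shift of the imputation Gaussian, in units of the
#'   column standard deviation (default 1.8)
#' @param impute_width width of the imputation Gaussian, in units of the
#'   column standard deviation (default 0.3)
#' @param fold_specific linear fold change required against every other group
#'   for cell-type-specific secretion (default 5)
#' @param fold_lysate linear fold change for lysate specificity (default 2.5)
#' @param max_other_detected exclusive-detection rule: at most this many
#'   replicates detected in every other group (default 2)
#' @param da_log2fc_min minimum |log2 fold change| for a differential call (default 2)
#' @param alpha significance level (default 0.05)
#' @param s0 fudge constant added to the t denominator in the permutation
#'   volcano test (default 0.1)
#' @param ei_min minimum disease-association evidence index (default 0.9)
#' @param seed integer seed for stochastic steps
#' @return a list of class `secretome_params`
#' @export
secretome_params <- function(min_detected = 5L, n_replicates = 6L,
                             impute_shift = 1.8, impute_width = 0.3,
                             fold_specific = 5, fold_lysate = 2.5,
                             max_other_detected = 2L,
                             da_log2fc_min = 2, alpha = 0.05, s0 = 0.1,
                             ei_min = 0.9, seed = 1L) {
  stopifnot(min_detected >= 1, min_detected <= n_replicates,
            impute_width > 0, fold_specific > 1, fold_lysate > 1,
            alpha > 0, alpha < 1, s0 >= 0, ei_min >= 0, ei_min <= 1)
  structure(list(min_detected = as.integer(min_detected),
                 n_replicates = as.integer(n_replicates),
                 impute_shift = impute_shift, impute_width = impute_width,
                 fold_specific = fold_specific, fold_lysate = fold_lysate,
                 max_other_detected = as.integer(max_other_detected),
                 da_log2fc_min = da_log2fc_min, alpha = alpha, s0 = s0,
                 ei_min = ei_min, seed = as.integer(seed)),
            class = "secretome_params")
}

#' @export
print.secretome_params <- function(x, ...) {
  cat("secretome_params:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
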