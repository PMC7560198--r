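#' Per-group detection counts
#'
#' Counts, for every protein and group, the replicates with a genuine
#' (pre-imputation) measurement. Counting always uses the `detected` mask
#' recorded at ingestion, so it is invariant under log transformation and
#' imputation.
#'
#' @param table an [intensity_table()]
#' @return a list of class `detection_counts`: `counts`, an integer matrix
#'   proteins x groups, and `totals`, the replicate count per group
#' @export
detection_counts <- function(table) {
  groups <- design_groups(table$design)
  counts <- vapply(groups, function(g)
    rowSums(table$detected[, table$design$group == g, drop = FALSE]),
    numeric(nrow(table$values)))
  counts <- matrix(as.integer(counts), nrow = nrow(table$values),
                   dimnames = list(rownames(table$values), groups))
  totals <- vapply(groups, function(g) sum(table$design$group == g), integer(1))
  structure(list(counts = counts, totals = totals), class = "detection_counts")
}

#' Per-protein per-group means
#'
#' Group means of an imputed log2 table, the abundance summary the
#' fold-change rules compare.
#'
#' @param table an imputed log2 [intensity_table()]
#' @return numeric matrix proteins x groups
#' @export
group_means <- function(table) {
  if (anyNA(table$values)) stop("group_means expects an imputed (complete) table")
  groups <- design_groups(table$design)
  m <- vapply(groups, function(g)
    rowMeans(table$values[, table$design$group == g, drop = FALSE]),
    numeric(nrow(table$values)))
  matrix(m, nrow = nrow(table$values),
         dimnames = list(rownames(table$values), groups))
}

#' Two-rule cell-type-specific secretion classifier
#'
#' A protein is called specific to group `g` when it is detected in at least
#' `min_detected` replicates of `g` and fulfils at least one of:
#' \describe{
#'   \item{rule i (exclusive detection)}{at most `max_other_detected`
#'     (default 2) replicates detected in every other group;}
#'   \item{rule ii (fold enrichment)}{its mean log2 intensity in `g`
#'     exceeds every other group's mean by at least `log2(fold_specific)`
#'     (default fivefold).}
#' }
#' Rule ii admits at most one group by strict dominance. If two groups both
#' satisfy rule i (possible only in degenerate detection patterns), the
#' protein is called none and the conflict is reported via a warning.
#'
#' @param counts a [detection_counts()] object
#' @param log2_means matrix of per-group means on the imputed log2 table
#'   (see [group_means()])
#' @param params a [secretome_params()]
#' @return a data.frame of class `specificity_calls`: `protein_id`,
#'   `specific_group` (`NA` for none), `rule` (one of `exclusive_detection`,
#'   `fold_enrichment`, `both`, `none`) and `min_pairwise_fold` (linear
#'   scale, `NA` when no group is called)
#' @export
classify_specificity <- function(counts, log2_means, params = secretome_params()) {
  cm <- counts$counts
  if (ncol(cm) < 2L) stop("specificity needs at least 2 groups")
  stopifnot(identical(rownames(cm), rownames(log2_means)),
            identical(colnames(cm), colnames(log2_means)))
  groups <- colnames(cm)
  n <- nrow(cm)
  specific <- rep(NA_character_, n)
  rule <- rep("none", n)
  fold <- rep(NA_real_, n)
  lfold_min <- log2(params$fold_specific)
  conflicts <- 0L
  for (i in seq_len(n)) {
    hit_g <- character(); hit_rule <- character(); hit_fold <- numeric()
    for (g in groups) {
      if (cm[i, g] < params$min_detected) next
      others <- setdiff(groups, g)
      r1 <- all(cm[i, others] <= params$max_other_detected)
      diffs <- log2_means[i, g] - log2_means[i, others]
      r2 <- all(diffs >= lfold_min)
      if (r1 || r2) {
        hit_g <- c(hit_g, g)
        hit_rule <- c(hit_rule, if (r1 && r2) "both"
                                else if (r1) "exclusive_detection"
                                else "fold_enrichment")
        hit_fold <- c(hit_fold, 2 ^ min(diffs))
      }
    }
    if (length(hit_g) == 1L) {
      specific[i] <- hit_g; rule[i] <- hit_rule; fold[i] <- hit_fold
    } else if (length(hit_g) > 1L) {
      conflicts <- conflicts + 1L   # two groups pass rule i: no unique origin
    }
  }
  if (conflicts)
    warning(conflicts, " protein(s) satisfied the exclusive-detection rule for ",
            "more than one group; called none")
  out <- data.frame(protein_id = rownames(cm), specific_group = specific,
                    rule = rule, min_pairwise_fold = fold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("specificity_calls", "data.frame")
  out
}

#' Uniquely detected proteins
#'
#' The descriptive counterpart of the specificity classifier: the group in
#' which a protein is detected at `min_detected` or more replicates when
#' exactly one group reaches that bar (any detection level is allowed in the
#' other groups, as long as they stay below `min_detected`). This is the
#' "detected in only one cell type" summary, deliberately distinct from the
#' two-rule cell-type-specific call.
#'
#' @param counts a [detection_counts()] object
#' @param min_detected detection bar (default 5)
#' @return a data.frame `protein_id`, `unique_group` (`NA` unless exactly
#'   one group reaches the bar) and `n_groups_detected` (number of groups at
#'   or above the bar)
#' @export
uniquely_detected <- function(counts, min_detected = 5L) {
  hits <- counts$counts >= min_detected
  n_groups <- rowSums(hits)
  grp <- rep(NA_character_, nrow(hits))
  one <- n_groups == 1L
  grp[one] <- colnames(hits)[apply(hits[one, , drop = FALSE], 1L, which)]
  data.frame(protein_id = rownames(counts$counts), unique_group = grp,
             n_groups_detected = as.integer(n_groups),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Lysate cell-type specificity (fold rule only)
#'
#' A protein is lysate-specific to group `g` when its mean log2 level in `g`
#' exceeds every other group's mean by at least `log2(fold_lysate)`
#' (default 2.5-fold). The table is expected to be filtered (the lysate
#' reanalysis uses a 2-replicate inclusion bar) and imputed with the same
#' left-shifted Gaussian procedure as the secretome.
#'
#' @param lysate_table an imputed log2 [intensity_table()]
#' @param params a [secretome_params()]
#' @return a data.frame `protein_id`, `lysate_group` (`NA` for none)
#' @export
lysate_specificity <- function(lysate_table, params = secretome_params()) {
  m <- group_means(lysate_table)
  lmin <- log2(params$fold_lysate)
  grp <- rep(NA_character_, nrow(m))
  for (g in colnames(m)) {
    diffs <- m[, g, drop = TRUE] - m[, setdiff(colnames(m), g), drop = FALSE]
    hit <- apply(diffs >= lmin, 1L, all)
    grp[hit] <- g                 # strict dominance: at most one group can win
  }
  data.frame(protein_id = rownames(m), lysate_group = grp,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Secretome-vs-lysate concordance
#'
#' Asks, for every cell-type-specifically secreted protein, whether its
#' specificity is already present at the expression level: a protein whose
#' lysate-specific group equals its secretome group is `expression_driven`;
#' one covered by the lysate dataset but not lysate-specific to the same
#' group is `secretion_specific` (pointing to a cell-type-specific release
#' mechanism such as selective shedding); one absent from the lysate
#' dataset is `secretome_only`.
#'
#' @param secretome_calls a `specificity_calls` data.frame
#'   (see [classify_specificity()]); only called proteins are compared
#' @param lysate_calls data.frame from [lysate_specificity()], covering the
#'   whole lysate universe (called or not)
#' @return a list: `calls`, a data.frame `protein_id`, `secretome_group`,
#'   `lysate_specific_group`, `category`; and `fractions`, per secretome
#'   group the fraction of lysate-covered proteins that are expression
#'   driven
#' @export
concordance <- function(secretome_calls, lysate_calls) {
  sec <- secretome_calls[!is.na(secretome_calls$specific_group), , drop = FALSE]
  lys <- stats::setNames(lysate_calls$lysate_group, lysate_calls$protein_id)
  in_lysate <- sec$protein_id %in% lysate_calls$protein_id
  lg <- ifelse(in_lysate, lys[sec$protein_id], NA_character_)
  category <- ifelse(!in_lysate, "secretome_only",
                     ifelse(!is.na(lg) & lg == sec$specific_group,
                            "expression_driven", "secretion_specific"))
  calls <- data.frame(protein_id = sec$protein_id,
                      secretome_group = sec$specific_group,
                      lysate_specific_group = lg,
                      category = category,
                      stringsAsFactors = FALSE, row.names = NULL)
  covered <- calls[calls$category != "secretome_only", , drop = FALSE]
  fractions <- vapply(split(covered$category, covered$secretome_group),
                      function(x) mean(x == "expression_driven"), numeric(1))
  list(calls = calls, fractions = fractions)
}
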