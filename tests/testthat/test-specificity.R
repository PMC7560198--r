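make_counts <- function(mat, totals = NULL) {
  if (is.null(totals)) totals <- stats::setNames(rep(6L, ncol(mat)), colnames(mat))
  structure(list(counts = mat, totals = totals), class = "detection_counts")
}

test_that("detection counts are exact and ignore imputation", {
  vals <- matrix(NA_real_, 2, 24)
  vals[1, 1:6] <- 100                      # all 6 neuron replicates
  groups <- c("neuron", "astro", "micro", "oligo")
  tab <- toy_table(vals[1, , drop = FALSE], groups)
  dc <- detection_counts(tab)
  expect_equal(unname(dc$counts[1, ]), c(6L, 0L, 0L, 0L))
  # all-missing protein counts zero everywhere
  tab2 <- toy_table(matrix(NA_real_, 1, 24), groups)
  expect_true(all(detection_counts(tab2)$counts == 0L))
  # oracle equality on synthetic data
  sim <- generate_secretome(sim_config(n_proteins = 400, seed = 17))
  expect_identical(detection_counts(sim$table)$counts,
                   oracle_detection_counts(sim$table))
})

test_that("the two specificity rules fire as specified", {
  groups <- c("astrocyte", "microglia", "neuron", "oligodendrocyte")
  cm <- matrix(c(1, 6, 0, 1,        # microglia exclusive (others <= 2)
                 6, 6, 6, 6,        # everywhere, neuron wins on fold
                 6, 6, 6, 6,        # everywhere, no fold dominance
                 4, 1, 0, 0),       # below the 5-replicate bar
               4, 4, byrow = TRUE, dimnames = list(paste0("P", 1:4), groups))
  means <- matrix(20, 4, 4, dimnames = dimnames(cm))
  means[2, "neuron"] <- 20 + log2(5) + 0.01
  calls <- classify_specificity(make_counts(cm), means)
  expect_equal(calls$specific_group, c("microglia", "neuron", NA, NA))
  expect_equal(calls$rule, c("exclusive_detection", "fold_enrichment", "none", "none"))
  expect_gte(calls$min_pairwise_fold[2], 5)
  # a rule-i call that also dominates on fold is labeled both
  means[1, "microglia"] <- 30
  calls2 <- classify_specificity(make_counts(cm), means)
  expect_equal(calls2$rule[1], "both")
})

test_that("two groups passing exclusive detection yield a logged conflict and no call", {
  # only reachable when the detection bar does not exceed the exclusion bar,
  # e.g. the lysate-style 2-replicate inclusion setting
  groups <- c("a", "b", "c")
  cm <- matrix(c(2, 2, 0), 1, 3, dimnames = list("P1", groups))
  means <- matrix(20, 1, 3, dimnames = dimnames(cm))
  params <- secretome_params(min_detected = 2)
  expect_warning(calls <- classify_specificity(make_counts(cm), means, params),
                 "more than one group")
  expect_true(is.na(calls$specific_group))
  expect_equal(calls$rule, "none")
})

test_that("classifier equals the brute-force oracle on random instances", {
  for (seed in c(3, 7, 19)) {
    sim <- generate_secretome(sim_config(n_proteins = 200, seed = seed))
    filt <- filter_by_replication(sim$table, 5)
    imp <- impute_left_shifted(log_transform(filt, 2), seed = seed)
    dc <- detection_counts(filt)
    means <- group_means(imp)
    calls <- suppressWarnings(classify_specificity(dc, means))
    oracle <- oracle_classify(dc$counts, means)
    expect_identical(calls$specific_group, oracle)
  }
})

test_that("threshold monotonicity: fold up shrinks, detection bar down grows", {
  sim <- generate_secretome(sim_config(n_proteins = 500, seed = 23))
  filt <- filter_by_replication(sim$table, 5)
  imp <- impute_left_shifted(log_transform(filt, 2), seed = 1)
  dc <- detection_counts(filt)
  means <- group_means(imp)
  base <- suppressWarnings(classify_specificity(dc, means, secretome_params()))
  tighter <- suppressWarnings(classify_specificity(dc, means,
                                                   secretome_params(fold_specific = 10)))
  fold_set <- function(x) x$protein_id[x$rule %in% c("fold_enrichment", "both")]
  expect_true(all(fold_set(tighter) %in% fold_set(base)))
  looser <- suppressWarnings(classify_specificity(dc, means,
                                                  secretome_params(min_detected = 4)))
  excl_set <- function(x) x$protein_id[x$rule %in% c("exclusive_detection", "both")]
  expect_true(all(excl_set(base) %in% excl_set(looser)))
})

test_that("uniquely-detected is a different notion than cell-type-specific", {
  groups <- c("a", "b", "c", "d")
  # detected >= 5 in exactly one group but 4 elsewhere: unique, not exclusive-rule
  cm <- matrix(c(6, 4, 4, 4), 1, 4, dimnames = list("P1", groups))
  u <- uniquely_detected(make_counts(cm), 5)
  expect_equal(u$unique_group, "a")
  expect_equal(u$n_groups_detected, 1L)
  means <- matrix(20, 1, 4, dimnames = dimnames(cm))
  calls <- classify_specificity(make_counts(cm), means)
  expect_true(is.na(calls$specific_group))
})

test_that("lysate specificity applies the 2.5-fold dominance rule", {
  groups <- c("astro", "micro", "neuron", "oligo")
  set.seed(4)
  vals <- matrix(rnorm(2 * 24, 20, 0.05), 2, 24,
                 dimnames = list(c("P1", "P2"), NULL))
  oligo_cols <- 19:24
  vals[1, oligo_cols] <- vals[1, oligo_cols] + log2(3)    # 3-fold up
  vals[2, oligo_cols] <- vals[2, oligo_cols] + log2(2)    # only 2-fold
  tab <- toy_table(vals, groups); tab$scale <- "log2"
  out <- lysate_specificity(tab)
  expect_equal(out$lysate_group, c("oligo", NA))
})

test_that("concordance categories and fractions follow the call pair", {
  sec <- data.frame(protein_id = c("P1", "P2", "P3", "P4"),
                    specific_group = c("neuron", "neuron", "astro", NA),
                    rule = c("both", "fold_enrichment", "both", "none"),
                    min_pairwise_fold = c(6, 8, 9, NA),
                    stringsAsFactors = FALSE)
  lys <- data.frame(protein_id = c("P1", "P2", "Px"),
                    lysate_group = c("neuron", NA, "micro"),
                    stringsAsFactors = FALSE)
  out <- concordance(sec, lys)
  expect_equal(out$calls$category, c("expression_driven", "secretion_specific",
                                     "secretome_only"))
  expect_equal(unname(out$fractions["neuron"]), 0.5)
  # invariant: expression_driven exactly when the groups agree
  agree <- with(out$calls, !is.na(lysate_specific_group) &
                  lysate_specific_group == secretome_group)
  expect_equal(out$calls$category == "expression_driven", agree)
})

test_that("planted lysate effects above the fold bar are recovered", {
  params <- secretome_params()
  sim <- generate_secretome(sim_config(n_proteins = 600, seed = 29,
                                       effect_log2 = log2(2.5) + 1,
                                       frac_cts = 0.3, censor_mid = 20))
  filt <- filter_by_replication(sim$table, 2)
  imp <- impute_left_shifted(log_transform(filt, 2), seed = 2)
  out <- lysate_specificity(imp, params)
  truth <- sim$truth$cts_group[match(out$protein_id, sim$truth$protein_id)]
  planted <- !is.na(truth)
  hit <- !is.na(out$lysate_group) & out$lysate_group == truth
  expect_gt(mean(hit[planted]), 0.9)                    # sensitivity
  expect_lt(mean(!is.na(out$lysate_group[!planted])), 0.02)  # false calls
})
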