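test_that("pearson matrix is exact on toys and guards sparse pairs", {
  set.seed(1)
  vals <- matrix(rnorm(10, 25, 2), 5, 2)
  vals[, 2] <- 3 * vals[, 1] + 1          # affine transform
  tab <- toy_table(vals, c("a", "b")); tab$scale <- "log2"
  cm <- pearson_matrix(tab, "complete")
  expect_equal(unname(diag(cm)), c(1, 1))
  expect_equal(cm[1, 2], 1)

  vals2 <- matrix(rnorm(10, 25, 2), 5, 2)
  tab2 <- toy_table(vals2, c("a", "b")); tab2$scale <- "log2"
  cm2 <- pearson_matrix(tab2, "complete")
  # brute-force covariance formula
  x <- vals2[, 1]; y <- vals2[, 2]
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cm2[1, 2], r, tolerance = 1e-12)
  expect_identical(cm2, t(cm2))

  vals3 <- matrix(rnorm(10, 25, 2), 5, 2)
  vals3[1:3, 1] <- NA                     # only 2 shared values
  tab3 <- toy_table(vals3, c("a", "b")); tab3$scale <- "log2"
  expect_warning(cm3 <- pearson_matrix(tab3, "pairwise"), "fewer than 3")
  expect_true(is.na(cm3[1, 2]))
  expect_equal(diag(cm3), c(a_1 = 1, b_1 = 1))
})

test_that("moderated test agrees with the independent limma implementation", {
  skip_if_not_installed("limma")
  sim <- generate_secretome(sim_config(n_proteins = 300, seed = 31,
                                       groups = c("a", "b"), censor_mid = 0))
  tab <- log_transform(sim$table, 2)
  res <- moderated_pairwise_da(tab, "a", "b")
  design <- cbind(1, tab$design$group == "a")
  fit <- limma::eBayes(limma::lmFit(tab$values, design))
  expect_equal(res$log2_fold_change, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(attr(res, "prior")$df_prior, fit$df.prior, tolerance = 1e-6)
  expect_equal(res$t_stat, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("moderated test: flat proteins give t = 0, p = 1; tiny tables fall back to plain t", {
  vals <- matrix(c(1, 2, 3, 1, 2, 3) + 20, 1, 6)
  rownames(vals) <- "P001"
  tab <- toy_table(vals, c("a", "b")); tab$scale <- "log2"
  res <- moderated_pairwise_da(tab, "a", "b")
  expect_equal(res$log2_fold_change, 0)
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)
  # single-protein table: no shrinkage possible, equals the classical t
  set.seed(2)
  vals2 <- matrix(rnorm(6, 25, 1), 1, 6, dimnames = list("P001", NULL))
  tab2 <- toy_table(vals2, c("a", "b")); tab2$scale <- "log2"
  res2 <- moderated_pairwise_da(tab2, "a", "b")
  ct <- stats::t.test(vals2[1, 1:3], vals2[1, 4:6], var.equal = TRUE)
  expect_equal(res2$t_stat, unname(ct$statistic), tolerance = 1e-9)
  expect_equal(res2$p_value, ct$p.value, tolerance = 1e-9)
})

test_that("moderated t interpolates monotonically between plain t and z", {
  sim <- generate_secretome(sim_config(n_proteins = 50, seed = 8,
                                       groups = c("a", "b"), censor_mid = 0))
  tab <- log_transform(sim$table, 2)
  plain <- moderated_pairwise_da(tab, "a", "b", df_prior = 0)
  pooled <- moderated_pairwise_da(tab, "a", "b", df_prior = Inf)
  grid <- c(0, 0.5, 2, 8, 32, Inf)
  tmat <- sapply(grid, function(d0)
    abs(moderated_pairwise_da(tab, "a", "b", df_prior = d0)$t_stat))
  expect_equal(tmat[, 1], abs(plain$t_stat))
  expect_equal(tmat[, ncol(tmat)], abs(pooled$t_stat))
  # |t| moves monotonically along the d0 grid for every protein
  mono <- apply(tmat, 1, function(x) all(diff(x) >= -1e-12) || all(diff(x) <= 1e-12))
  expect_true(all(mono))
})

test_that("significance needs both the Bonferroni p and the fold-change bar", {
  sim <- generate_secretome(sim_config(n_proteins = 200, seed = 12,
                                       groups = c("a", "b"), censor_mid = 0,
                                       frac_cts = 0.2, effect_log2 = 3))
  tab <- log_transform(sim$table, 2)
  res <- moderated_pairwise_da(tab, "a", "b")
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_true(all(abs(res$log2_fold_change[res$significant]) >= 2))
  expect_true(all(res$p_adjusted[res$significant] < 0.05))
  # planted effects on "a" are found
  planted_a <- !is.na(sim$truth$cts_group) & sim$truth$cts_group == "a"
  expect_gt(mean(res$significant[planted_a]), 0.8)
})

test_that("s0 = 0 reduces the modified t to the classical t", {
  sim <- generate_secretome(sim_config(n_proteins = 100, seed = 13,
                                       censor_mid = 0))
  tab <- log_transform(sim$table, 2)
  s0res <- s0_permutation_test(tab, "neuron", "astrocyte", s0 = 0, seed = 1)
  plain <- plain_two_sample_t(tab, "neuron", "astrocyte")
  expect_equal(s0res$t_stat, plain$t_stat, tolerance = 1e-12)
})

test_that("plain two-sample t matches the textbook computation", {
  vals <- matrix(c(22.1, 23.4, 22.8, 25.0, 25.9, 25.3), 1, 6,
                 dimnames = list("P001", NULL))
  tab <- toy_table(vals, c("a", "b")); tab$scale <- "log2"
  res <- plain_two_sample_t(tab, "a", "b")
  ct <- stats::t.test(vals[1, 1:3], vals[1, 4:6], var.equal = TRUE)
  expect_equal(res$t_stat, unname(ct$statistic), tolerance = 1e-9)
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-9)
  expect_equal(res$log2_fold_change, mean(vals[1, 1:3]) - mean(vals[1, 4:6]))
  # identical groups give p = 1
  flat <- toy_table(matrix(c(1, 2, 3, 1, 2, 3) + 20, 1, 6,
                           dimnames = list("P001", NULL)), c("a", "b"))
  flat$scale <- "log2"
  expect_equal(plain_two_sample_t(flat, "a", "b")$p_value, 1)
})

test_that("permutation FDR is invariant to protein order and within-group relabeling", {
  sim <- generate_secretome(sim_config(n_proteins = 120, seed = 14,
                                       censor_mid = 0))
  tab <- log_transform(sim$table, 2)
  a <- s0_permutation_test(tab, "neuron", "microglia", seed = 7)
  perm <- rev(seq_len(nrow(tab$values)))
  tab2 <- subset_proteins(tab, perm)
  b <- s0_permutation_test(tab2, "neuron", "microglia", seed = 7)
  expect_equal(attr(a, "cutoff"), attr(b, "cutoff"))
  expect_equal(a$significant, rev(b$significant))
  # swap two replicates within a group: same observed statistics
  sw <- seq_len(ncol(tab$values))
  i1 <- which(tab$design$group == "neuron")[1:2]
  sw[i1] <- rev(i1)
  tab3 <- intensity_table(tab$values[, sw], as_sample_design(tab$design[sw, ]),
                          "log2")
  cc <- s0_permutation_test(tab3, "neuron", "microglia", seed = 7)
  expect_equal(sort(cc$t_stat), sort(a$t_stat), tolerance = 1e-12)
})

test_that("few-sample contrasts fall back to exhaustive permutation with a warning", {
  sim <- generate_secretome(sim_config(n_proteins = 50, seed = 15,
                                       groups = c("a", "b"), n_replicates = 3,
                                       censor_mid = 0))
  tab <- log_transform(sim$table, 2)
  expect_warning(res <- s0_permutation_test(tab, "a", "b", seed = 1),
                 "enumerating exhaustively")
  expect_s3_class(res, "da_result")
})

test_that("proteins quantified in one condition only are listed as exclusive", {
  sim <- generate_secretome(sim_config(n_proteins = 60, seed = 16,
                                       groups = c("ctrl", "treated"),
                                       censor_mid = 0))
  tab <- sim$table
  tab$values[1, tab$design$group == "treated"] <- NA
  tab$detected[1, tab$design$group == "treated"] <- FALSE
  imp <- impute_left_shifted(log_transform(tab, 2), seed = 5)
  res <- moderated_pairwise_da(imp, "ctrl", "treated")
  excl <- attr(res, "exclusive")
  expect_equal(excl$only_A, rownames(tab$values)[1])
  expect_length(excl$only_B, 0)
})
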