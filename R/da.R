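# Differential abundance: moderated empirical-Bayes t, SAM-style s0
# permutation test, and the plain two-sample t. All tests are pairwise
# group contrasts on an imputed log2 table; proteins detected in only one
# of the two groups are listed separately (attribute "exclusive") rather
# than given a p-value driven purely by imputation.

group_split <- function(table, groupA, groupB) {
  groups <- design_groups(table$design)
  for (g in c(groupA, groupB))
    if (!g %in% groups) stop("unknown group: ", g)
  iA <- which(table$design$group == groupA)
  iB <- which(table$design$group == groupB)
  if (length(iA) < 2L || length(iB) < 2L)
    stop("both groups need at least 2 replicates")
  list(iA = iA, iB = iB)
}

# pooled-variance two-sample statistics, vectorized over proteins
pooled_stats <- function(vals, iA, iB) {
  nA <- length(iA); nB <- length(iB)
  mA <- rowMeans(vals[, iA, drop = FALSE])
  mB <- rowMeans(vals[, iB, drop = FALSE])
  ssA <- rowSums((vals[, iA, drop = FALSE] - mA)^2)
  ssB <- rowSums((vals[, iB, drop = FALSE] - mB)^2)
  df <- nA + nB - 2L
  s2 <- (ssA + ssB) / df
  list(lfc = mA - mB, s2 = s2, df = df, scale2 = 1 / nA + 1 / nB,
       nA = nA, nB = nB)
}

exclusive_proteins <- function(table, iA, iB) {
  dA <- rowSums(table$detected[, iA, drop = FALSE])
  dB <- rowSums(table$detected[, iB, drop = FALSE])
  list(only_A = rownames(table$values)[dA > 0 & dB == 0],
       only_B = rownames(table$values)[dB > 0 & dA == 0])
}

#' Invert the trigamma function
#'
#' Newton iteration on `trigamma(x) = y`, used when moment-matching the
#' scaled inverse-chi-square prior of the moderated t.
#'
#' @param y positive values
#' @return x with `trigamma(x) = y`
#' @export
trigamma_inverse <- function(y) {
  out <- y
  pos <- !is.na(y) & y > 0
  out[!pos & !is.na(y)] <- Inf
  x <- 0.5 + 1 / y[pos]           # good starting value for all y > 0
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[pos]) / psigamma(x, 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  out[pos] <- x
  out
}

# Moment-matching fit of the variance prior: s2_g ~ s2_prior * chisq_d/d
# scaled-F marginal; estimate (df_prior, s2_prior) from log s2_g.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(df_prior = 0, s2_prior = NA_real_))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1L) - trigamma(df / 2)
  if (evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    s2_prior <- exp(emean)
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

da_result <- function(protein_id, lfc, t_stat, df, p, p_adj, significant, method) {
  out <- data.frame(protein_id = protein_id, log2_fold_change = lfc,
                    t_stat = t_stat, df = df, p_value = p,
                    p_adjusted = p_adj, significant = significant,
                    stringsAsFactors = FALSE)
  out$method <- method
  rownames(out) <- NULL
  class(out) <- c("da_result", "data.frame")
  out
}

#' Moderated empirical-Bayes differential abundance test
#'
#' Protein-wise linear models with empirical-Bayes variance shrinkage for a
#' pairwise contrast `groupA - groupB`. Each protein's pooled residual
#' variance (degrees of freedom `nA + nB - 2`) is shrunk toward a prior
#' `(df_prior, s2_prior)` estimated by moment matching of `log s2` across
#' proteins (digamma/trigamma inversion); the moderated t has
#' `df + df_prior` degrees of freedom. A protein is significant when its
#' Bonferroni-corrected two-sided p-value is below `alpha` and its
#' |log2 fold change| is at least `da_log2fc_min` (default 2, chosen to
#' damp false positives caused by imputation). With fewer than 10 proteins
#' no shrinkage is attempted (`df_prior = 0`, ordinary t).
#'
#' @param table an imputed log2 [intensity_table()]
#' @param groupA,groupB group names; fold change is A minus B
#' @param params a [secretome_params()]
#' @param df_prior optional forced prior degrees of freedom (0 disables
#'   shrinkage; `Inf` fully pools); `NULL` estimates it from the data
#' @return a `da_result` data.frame, one row per protein; attributes
#'   `prior` (fitted df_prior/s2_prior) and `exclusive` (proteins detected
#'   in only one group, not assigned a p-value in the separate list)
#' @export
moderated_pairwise_da <- function(table, groupA, groupB,
                                  params = secretome_params(),
                                  df_prior = NULL) {
  idx <- group_split(table, groupA, groupB)
  vals <- table$values
  if (anyNA(vals)) stop("moderated test requires an imputed (complete) table")
  st <- pooled_stats(vals, idx$iA, idx$iB)
  if (mean(st$s2 == 0) > 0.9)
    stop("residual variance is zero for >90% of proteins; degenerate input")
  if (is.null(df_prior)) {
    prior <- if (nrow(vals) < 10L) list(df_prior = 0, s2_prior = NA_real_)
             else fit_variance_prior(st$s2, st$df)
  } else {
    prior <- list(df_prior = df_prior,
                  s2_prior = if (df_prior > 0) fit_variance_prior(st$s2, st$df)$s2_prior
                             else NA_real_)
  }
  d0 <- prior$df_prior
  s2_post <- if (d0 == 0) st$s2
             else if (is.infinite(d0)) rep(prior$s2_prior, length(st$s2))
             else (d0 * prior$s2_prior + st$df * st$s2) / (d0 + st$df)
  se <- sqrt(s2_post * st$scale2)
  t_stat <- st$lfc / se
  df_total <- st$df + d0
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_stat))
       else 2 * stats::pt(-abs(t_stat), df = df_total)
  p_adj <- pmin(1, p * length(p))
  sig <- p_adj < params$alpha & abs(st$lfc) >= params$da_log2fc_min
  out <- da_result(rownames(vals), st$lfc, t_stat, df_total, p, p_adj, sig,
                   "moderated_bonferroni")
  attr(out, "prior") <- prior
  attr(out, "exclusive") <- exclusive_proteins(table, idx$iA, idx$iB)
  out
}

# all |t| values for a matrix of A-membership indicators (columns = perms)
sam_t_matrix <- function(vals, assign_mat, s0) {
  n <- ncol(vals)
  nA <- colSums(assign_mat)
  nB <- n - nA
  df <- n - 2L
  sumsq_all <- rowSums(vals^2)
  sum_all <- rowSums(vals)
  sumA <- vals %*% assign_mat                    # proteins x perms
  sumsqA <- (vals^2) %*% assign_mat
  mA <- sweep(sumA, 2L, nA, "/")
  mB <- sweep(sum_all - sumA, 2L, nB, "/")
  ssA <- sumsqA - sweep(mA^2, 2L, nA, "*")
  ssB <- (sumsq_all - sumsqA) - sweep(mB^2, 2L, nB, "*")
  s2 <- (ssA + ssB) / df
  s2[s2 < 0] <- 0                                # numeric guard
  se <- sqrt(sweep(s2, 2L, 1 / nA + 1 / nB, "*"))
  (mA - mB) / (se + s0)
}

#' SAM-style s0 permutation test
#'
#' Two-sample test with a fudge constant `s0` added to the pooled standard
#' error of each protein's t denominator, so small fold changes cannot reach
#' significance on a tiny variance alone; the significance region in the
#' volcano plot is bounded by a hyperbolic curve. The cutoff on the modified
#' |t| is calibrated so that the permutation-estimated false discovery rate
#' (mean count of permuted-label proteins beyond the cutoff divided by the
#' observed count, with pi0 fixed at 1) is at most `alpha`. Group labels are
#' permuted over the combined samples; when fewer than 20 distinct
#' non-trivial label assignments exist they are enumerated exhaustively with
#' a warning, otherwise `n_perm` assignments are drawn (without replacement
#' when the universe is small enough to enumerate).
#'
#' @param table an imputed log2 [intensity_table()]
#' @param groupA,groupB group names; fold change is A minus B
#' @param s0 fudge constant on the standard-error scale (default 0.1)
#' @param alpha target FDR of the significance region (default 0.05)
#' @param n_perm number of label permutations (default 250)
#' @param seed integer seed
#' @return a `da_result` with modified t statistics; attributes `cutoff`
#'   (calibrated |t| threshold), `fdr_curve` (candidate cutoffs with
#'   estimated FDR) and `threshold_curve` (volcano-space boundary
#'   coordinates), plus `exclusive` as in [moderated_pairwise_da()]
#' @export
s0_permutation_test <- function(table, groupA, groupB, s0 = 0.1, alpha = 0.05,
                                n_perm = 250L, seed = 1L) {
  idx <- group_split(table, groupA, groupB)
  vals <- table$values[, c(idx$iA, idx$iB), drop = FALSE]
  if (anyNA(vals)) stop("s0 permutation test requires an imputed (complete) table")
  n <- ncol(vals)
  nA <- length(idx$iA)
  obs_assign <- matrix(c(rep(1, nA), rep(0, n - nA)), ncol = 1)
  t_obs <- drop(sam_t_matrix(vals, obs_assign, s0))

  universe <- choose(n, nA)
  n_nontrivial <- universe - (if (nA == n - nA) 2L else 1L)
  withr::local_seed(seed)
  if (n_nontrivial < 20L || universe <= max(n_perm, 2000L)) {
    combos <- utils::combn(n, nA)
    assign_mat <- matrix(0, n, ncol(combos))
    assign_mat[cbind(as.vector(combos),
                     rep(seq_len(ncol(combos)), each = nA))] <- 1
    obs_col <- which(colSums(assign_mat == obs_assign[, 1]) == n)
    assign_mat <- assign_mat[, -obs_col, drop = FALSE]
    if (nA == n - nA) {   # complement of the observed labeling gives the same |t|
      comp <- which(colSums(assign_mat == (1 - obs_assign[, 1])) == n)
      if (length(comp)) assign_mat <- assign_mat[, -comp, drop = FALSE]
    }
    if (n_nontrivial < 20L)
      warning("only ", ncol(assign_mat),
              " distinct label permutations; enumerating exhaustively")
    if (ncol(assign_mat) > n_perm)
      assign_mat <- assign_mat[, sample.int(ncol(assign_mat), n_perm), drop = FALSE]
  } else {
    assign_mat <- replicate(n_perm, {
      a <- numeric(n); a[sample.int(n, nA)] <- 1; a
    })
  }
  t_perm <- abs(sam_t_matrix(vals, assign_mat, s0))

  abs_obs <- abs(t_obs)
  cand <- sort(unique(abs_obs), decreasing = TRUE)
  n_obs_beyond <- vapply(cand, function(c) sum(abs_obs >= c), numeric(1))
  n_perm_beyond <- vapply(cand, function(c) mean(colSums(t_perm >= c)), numeric(1))
  fdr <- pmin(1, n_perm_beyond / n_obs_beyond)
  ok <- fdr <= alpha
  cutoff <- if (any(ok)) min(cand[ok]) else Inf
  sig <- abs_obs >= cutoff
  st <- pooled_stats(vals, seq_len(nA), seq(nA + 1L, n))
  p_plain <- 2 * stats::pt(-abs(st$lfc / sqrt(st$s2 * st$scale2)), df = st$df)
  out <- da_result(rownames(vals), st$lfc, t_obs, st$df, p_plain,
                   pmin(1, p_plain * length(p_plain)), sig, "s0_permutation")
  attr(out, "cutoff") <- cutoff
  attr(out, "fdr_curve") <- data.frame(cutoff = cand, n_significant = n_obs_beyond,
                                       fdr_estimate = fdr)
  attr(out, "threshold_curve") <- sam_threshold_curve(cutoff, s0, st$df, st$scale2)
  attr(out, "exclusive") <- exclusive_proteins(table, idx$iA, idx$iB)
  out
}

# volcano-space boundary: for each standard error se, the smallest |lfc|
# reaching the modified-t cutoff is cutoff*(s0 + se); its plain-t p-value
# gives the y coordinate of the hyperbola.
sam_threshold_curve <- function(cutoff, s0, df, scale2, n_points = 200L) {
  if (!is.finite(cutoff))
    return(data.frame(log2_fold_change = numeric(), neg_log10_p = numeric()))
  se <- seq(1e-3, 2, length.out = n_points)
  lfc <- cutoff * (s0 + se)
  p <- 2 * stats::pt(-lfc / se, df = df)
  data.frame(log2_fold_change = lfc, neg_log10_p = -log10(p))
}

#' Plain two-sample t-test per protein
#'
#' Classical pooled-variance two-sample t for a pairwise contrast, two-sided
#' p-values, significance flagged at `p < alpha` without multiplicity
#' correction (the volcano convention for the condition-vs-control brain
#' slice comparison).
#'
#' @param table an imputed log2 [intensity_table()]
#' @param groupA,groupB group names; fold change is A minus B
#' @param alpha significance level (default 0.05)
#' @return a `da_result`; attribute `exclusive` as in
#'   [moderated_pairwise_da()]
#' @export
plain_two_sample_t <- function(table, groupA, groupB, alpha = 0.05) {
  idx <- group_split(table, groupA, groupB)
  vals <- table$values
  if (anyNA(vals)) stop("two-sample t requires an imputed (complete) table")
  st <- pooled_stats(vals, idx$iA, idx$iB)
  t_stat <- st$lfc / sqrt(st$s2 * st$scale2)
  p <- 2 * stats::pt(-abs(t_stat), df = st$df)
  out <- da_result(rownames(vals), st$lfc, t_stat, st$df, p, p,
                   p < alpha, "two_sample_t")
  attr(out, "exclusive") <- exclusive_proteins(table, idx$iA, idx$iB)
  out
}
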