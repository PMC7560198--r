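# Synthetic secretome generator with planted ground truth. Emulates the
# statistical structure the analysis assumes: log-normal protein abundance,
# cell-type-specific enrichment effects, replicate noise, and
# intensity-dependent left-censored (MNAR) missingness via a logistic
# detection model, plus UniProt-style annotation/topology structure and
# tryptic/semi-tryptic peptides.

#' Simulation configuration
#'
#' Defaults mirror the study design the pipeline targets: 4 brain cell
#' types x 6 biological replicates, log2 abundances around 25 (SD 2),
#' 30% of proteins planted as cell-type-specifically secreted with an
#' eightfold (log2 = 3) enrichment — comfortably above the fivefold calling
#' threshold — replicate SD 0.5, and logistic detection centered at log2
#' intensity 22 with slope 1.5 so low-abundance proteins go missing first.
#' Annotation fractions (45% soluble secreted, 40% single-pass TM, 5%
#' GPI-anchored) echo a shedding-rich secretome.
#'
#' @param n_proteins number of proteins (default 2000)
#' @param groups group names (default the four brain cell types)
#' @param n_replicates replicates per group (default 6)
#' @param base_mean,base_sd log2 abundance distribution (defaults 25, 2)
#' @param frac_cts fraction of proteins with a planted specific group (default 0.3)
#' @param effect_log2 planted log2 enrichment (default log2(8))
#' @param replicate_sd replicate noise SD on log2 scale (default 0.5)
#' @param censor_mid log2 intensity of 50% detection (default 22)
#' @param censor_slope logistic slope of the detection model (default 1.5)
#' @param hard_censoring if TRUE, detection is a hard threshold at
#'   `censor_mid` instead of logistic
#' @param frac_secreted,frac_single_tm,frac_gpi annotation fractions
#'   (defaults 0.45, 0.40, 0.05; remainder is intracellular background)
#' @param leakage probability that an intracellular-domain peptide leaks
#'   into the peptide output (default 0.001)
#' @param seed integer seed
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_proteins = 2000L,
                       groups = c("astrocyte", "microglia", "neuron", "oligodendrocyte"),
                       n_replicates = 6L, base_mean = 25, base_sd = 2,
                       frac_cts = 0.3, effect_log2 = log2(8),
                       replicate_sd = 0.5, censor_mid = 22, censor_slope = 1.5,
                       hard_censoring = FALSE,
                       frac_secreted = 0.45, frac_single_tm = 0.40,
                       frac_gpi = 0.05, leakage = 0.001, seed = 1L) {
  stopifnot(n_proteins >= 1, length(groups) >= 1, n_replicates >= 1,
            frac_cts >= 0, frac_cts <= 1, replicate_sd > 0,
            frac_secreted >= 0, frac_single_tm >= 0, frac_gpi >= 0,
            frac_secreted + frac_single_tm + frac_gpi <= 1,
            leakage >= 0, leakage <= 1)
  structure(list(n_proteins = as.integer(n_proteins), groups = groups,
                 n_replicates = as.integer(n_replicates),
                 base_mean = base_mean, base_sd = base_sd,
                 frac_cts = frac_cts, effect_log2 = effect_log2,
                 replicate_sd = replicate_sd, censor_mid = censor_mid,
                 censor_slope = censor_slope, hard_censoring = hard_censoring,
                 frac_secreted = frac_secreted, frac_single_tm = frac_single_tm,
                 frac_gpi = frac_gpi, leakage = leakage,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_ids <- function(n) sprintf("SP%05d", seq_len(n))

#' Generate a synthetic secretome with planted truth
#'
#' For protein i, group g, replicate r the latent log2 intensity is
#' `base_i + effect * [g == cts_i] + Normal(0, replicate_sd^2)`; the value
#' is observed with probability `logistic((latent - censor_mid) *
#' censor_slope)` (or iff `latent >= censor_mid` under hard censoring) and
#' reported on the raw scale as `2^latent`. Everything is reproducible from
#' the seed.
#'
#' @param config a [sim_config()]
#' @return a list: `table`, a raw-scale [intensity_table()]; `truth`, a
#'   `sim_truth` list with per-protein `cts_group`, `base`, the latent
#'   group-mean matrix and the config
#' @export
generate_secretome <- function(config = sim_config()) {
  withr::local_seed(config$seed)
  n <- config$n_proteins
  ids <- sim_ids(n)
  groups <- config$groups
  base <- stats::rnorm(n, config$base_mean, config$base_sd)
  cts <- rep(NA_character_, n)
  n_cts <- round(config$frac_cts * n)
  if (n_cts > 0)
    cts[sample.int(n, n_cts)] <- sample(groups, n_cts, replace = TRUE)
  design <- sample_design(
    paste(rep(groups, each = config$n_replicates),
          rep(seq_len(config$n_replicates), length(groups)), sep = "_"),
    rep(groups, each = config$n_replicates),
    rep(seq_len(config$n_replicates), length(groups)))
  mean_mat <- outer(base, rep(1, length(groups)))
  dimnames(mean_mat) <- list(ids, groups)
  for (g in groups)
    mean_mat[, g] <- mean_mat[, g] + config$effect_log2 * (!is.na(cts) & cts == g)
  latent <- mean_mat[, design$group, drop = FALSE] +
    matrix(stats::rnorm(n * nrow(design), 0, config$replicate_sd), n)
  detect_p <- if (config$hard_censoring) (latent >= config$censor_mid) * 1
              else stats::plogis((latent - config$censor_mid) * config$censor_slope)
  observed <- matrix(stats::runif(length(latent)) < detect_p, n)
  if (!any(observed)) stop("degenerate config: every value censored")
  vals <- 2 ^ latent
  vals[!observed] <- NA_real_
  dimnames(vals) <- list(ids, design$sample_id)
  table <- intensity_table(vals, design, scale = "raw")
  truth <- structure(list(protein_id = ids, cts_group = cts, base = base,
                          group_means = mean_mat, config = config),
                     class = "sim_truth")
  list(table = table, truth = truth)
}

#' Generate annotations, topology and sequences for simulated proteins
#'
#' Assigns each protein an annotation category by the configured fractions:
#' soluble secreted, single-pass transmembrane (random type-I/type-II
#' orientation, a 21-residue TM segment, extracellular and intracellular
#' segments filling the rest), GPI-anchored (fully extracellular), or
#' intracellular background (cytoplasm keyword). Secreted, TM and GPI
#' proteins carry the glycoprotein keyword with probability 0.8, emulating
#' a glyco-enriched secretome. Sequences are uniform-random amino acids of
#' length 200-800.
#'
#' @param truth a `sim_truth` from [generate_secretome()]
#' @return a list: `annotations`, a data.frame in [read_annotations()]
#'   layout; `sequences`, a named character vector
#' @export
generate_annotations_topology <- function(truth) {
  config <- truth$config
  withr::local_seed(config$seed + 1L)
  n <- length(truth$protein_id)
  cat_p <- c(secreted = config$frac_secreted, single_tm = config$frac_single_tm,
             gpi = config$frac_gpi)
  cat_p <- c(cat_p, background = 1 - sum(cat_p))
  category <- sample(names(cat_p), n, replace = TRUE, prob = cat_p)
  lens <- sample(200:800, n, replace = TRUE)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sequences <- vapply(lens, function(L)
    paste(sample(aa, L, replace = TRUE), collapse = ""), character(1))
  names(sequences) <- truth$protein_id
  keywords <- vector("list", n)
  topology <- vector("list", n)
  glyco <- stats::runif(n) < 0.8
  empty_topo <- data.frame(kind = character(), start = integer(), end = integer(),
                           stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    L <- lens[i]
    kw <- character(); topo <- empty_topo
    if (category[i] == "secreted") {
      kw <- "secreted"
      topo <- data.frame(kind = "extracellular", start = 1L, end = L)
    } else if (category[i] == "single_tm") {
      kw <- c("membrane", "transmembrane_single_pass")
      tm_start <- sample(seq(30L, L - 50L), 1L)
      type1 <- stats::runif(1) < 0.5    # type I: N-terminus extracellular
      topo <- data.frame(
        kind = if (type1) c("extracellular", "transmembrane", "intracellular")
               else c("intracellular", "transmembrane", "extracellular"),
        start = c(1L, tm_start, tm_start + 21L),
        end = c(tm_start - 1L, tm_start + 20L, L))
    } else if (category[i] == "gpi") {
      kw <- c("gpi_anchor", "membrane")
      topo <- data.frame(kind = "extracellular", start = 1L, end = L)
    } else {
      kw <- "cytoplasm"
    }
    if (category[i] != "background" && glyco[i]) kw <- c(kw, "glycoprotein")
    keywords[[i]] <- kw
    topology[[i]] <- topo
  }
  annotations <- data.frame(protein_id = truth$protein_id,
                            sequence_length = lens, stringsAsFactors = FALSE)
  annotations$keywords <- keywords
  annotations$topology <- topology
  list(annotations = annotations, sequences = sequences)
}

#' Generate secretome peptides from simulated proteins
#'
#' Performs a full tryptic digest (up to 2 missed cleavages, length 6-30)
#' of every single-pass TM protein and keeps the peptides lying entirely
#' within an extracellular segment (a shed ectodomain carries no
#' transmembrane residues), emulating a shedding-dominated secretome; peptides
#' lying entirely in the intracellular domain leak through with probability
#' `leakage`. Optional planted cleavage positions split every tryptic
#' peptide spanning the cut into its two semi-tryptic fragments (the
#' spanning parent is removed), so a cleavage caller should flag exactly
#' those fragments.
#'
#' @param sequences named character vector from
#'   [generate_annotations_topology()]
#' @param annotations matching annotation data.frame
#' @param leakage intracellular leak-through probability (default from a
#'   shedding-dominated secretome, 0.001)
#' @param planted_cuts named list, protein id -> integer cleavage positions
#'   (cut after that residue)
#' @param seed integer seed
#' @return a peptide data.frame; attribute `planted_fragments` marks rows
#'   created by splitting at a planted cut
#' @export
generate_peptides <- function(sequences, annotations, leakage = 0.001,
                              planted_cuts = NULL, seed = 1L) {
  withr::local_seed(seed)
  idx <- annotation_index(annotations)
  single_tm <- has_keyword(annotations, "transmembrane_single_pass")
  out <- list()
  planted <- logical()
  for (pid in names(sequences)) {
    j <- idx[pid]
    if (is.na(j) || !single_tm[j]) next
    topo <- annotations$topology[[j]]
    pep <- tryptic_digest(sequences[[pid]], pid)
    if (!nrow(pep)) next
    cuts <- planted_cuts[[pid]]
    is_frag <- rep(FALSE, nrow(pep))
    if (!is.null(cuts)) {
      for (cut in cuts) {
        span <- pep$start <= cut & pep$end > cut & !is_frag
        if (!any(span)) next
        frags <- do.call(rbind, lapply(which(span), function(k)
          split_at_cut(pep[k, ], cut, sequences[[pid]])))
        pep <- rbind(pep[!span, , drop = FALSE], frags)
        is_frag <- c(is_frag[!span], rep(TRUE, nrow(frags)))
      }
      dup <- duplicated(paste(pep$start, pep$end))
      pep <- pep[!dup, , drop = FALSE]; is_frag <- is_frag[!dup]
    }
    ex <- topo[topo$kind == "extracellular", , drop = FALSE]
    ic <- topo[topo$kind == "intracellular", , drop = FALSE]
    in_ex <- within_any(pep$start, pep$end, ex)
    in_ic <- within_any(pep$start, pep$end, ic)
    keep <- in_ex | (in_ic & stats::runif(nrow(pep)) < leakage) | is_frag
    out[[length(out) + 1L]] <- pep[keep, , drop = FALSE]
    planted <- c(planted, is_frag[keep])
  }
  peptides <- if (length(out)) do.call(rbind, out)
    else data.frame(protein_id = character(), sequence = character(),
                    start = integer(), end = integer(),
                    aa_before = character(), aa_after = character(),
                    stringsAsFactors = FALSE)
  rownames(peptides) <- NULL
  attr(peptides, "planted_fragments") <- planted
  peptides
}

split_at_cut <- function(pep, cut, sequence) {
  len <- nchar(sequence)
  mk <- function(s, e) data.frame(
    protein_id = pep$protein_id, sequence = substr(sequence, s, e),
    start = s, end = e,
    aa_before = if (s == 1L) "-" else substr(sequence, s - 1L, s - 1L),
    aa_after = if (e == len) "-" else substr(sequence, e + 1L, e + 1L),
    stringsAsFactors = FALSE)
  rbind(mk(pep$start, cut), mk(cut + 1L, pep$end))
}

overlaps_any <- function(s, e, seg) {
  if (!nrow(seg)) return(rep(FALSE, length(s)))
  vapply(seq_along(s), function(i)
    any(s[i] <= seg$end & e[i] >= seg$start), logical(1))
}

within_any <- function(s, e, seg) {
  if (!nrow(seg)) return(rep(FALSE, length(s)))
  vapply(seq_along(s), function(i)
    any(s[i] >= seg$start & e[i] <= seg$end), logical(1))
}

#' Generate a synthetic body-fluid proteome from the simulated secretome
#'
#' Models the fluid (e.g. CSF) as a mixture of the cell-type secretomes:
#' each protein's latent fluid abundance is the log2 of the weighted sum of
#' its linear-scale cell-type means, plus replicate noise; the same
#' logistic censoring model applies. Default weights are uniform over the
#' cell types.
#'
#' @param truth a `sim_truth` from [generate_secretome()]
#' @param weights named nonnegative weights over the cell types (default
#'   uniform, summing to 1)
#' @param n_replicates fluid replicates (default 4)
#' @param noise_sd replicate noise SD (default the config's replicate_sd)
#' @param group fluid group name (default "csf")
#' @param seed integer seed (default config seed + 2)
#' @return a raw-scale [intensity_table()]
#' @export
generate_fluid <- function(truth, weights = NULL, n_replicates = 4L,
                           noise_sd = NULL, group = "csf", seed = NULL) {
  config <- truth$config
  groups <- config$groups
  if (is.null(weights)) weights <- stats::setNames(rep(1 / length(groups), length(groups)), groups)
  stopifnot(all(names(weights) %in% groups), all(weights >= 0), sum(weights) > 0)
  if (is.null(noise_sd)) noise_sd <- config$replicate_sd
  if (is.null(seed)) seed <- config$seed + 2L
  withr::local_seed(seed)
  lin <- 2 ^ truth$group_means
  fluid_mean <- log2(as.vector(lin[, names(weights), drop = FALSE] %*% weights))
  n <- length(fluid_mean)
  design <- sample_design(paste(group, seq_len(n_replicates), sep = "_"),
                          group, seq_len(n_replicates))
  latent <- outer(fluid_mean, rep(1, n_replicates)) +
    matrix(stats::rnorm(n * n_replicates, 0, noise_sd), n)
  detect_p <- if (config$hard_censoring) (latent >= config$censor_mid) * 1
              else stats::plogis((latent - config$censor_mid) * config$censor_slope)
  observed <- matrix(stats::runif(length(latent)) < detect_p, n)
  if (!any(observed)) stop("degenerate config: every fluid value censored")
  vals <- 2 ^ latent
  vals[!observed] <- NA_real_
  dimnames(vals) <- list(truth$protein_id, design$sample_id)
  intensity_table(vals, design, scale = "raw")
}
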