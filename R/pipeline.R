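# End-to-end orchestration: preprocess -> statistics -> specificity ->
# topology -> fluid mapping -> interaction map, with a JSON summary and a
# MANIFEST recording which stages completed.

#' Run the secretome analysis pipeline
#'
#' Chains the pipeline stages on in-memory inputs and, optionally, writes
#' the stage outputs (TSV), a JSON summary of the headline counters and a
#' MANIFEST to `out_dir`. Stages are toggled by presence of their inputs:
#' topology mapping needs `peptides` + `annotations`, fluid mapping needs
#' `fluid_table`, the interaction map needs `lysate_table` +
#' `interactions`.
#'
#' @param secretome_table a raw-scale [intensity_table()]
#' @param params a [secretome_params()]
#' @param annotations optional annotation data.frame
#' @param sequences optional named character vector of protein sequences
#' @param peptides optional peptide data.frame
#' @param lysate_table optional raw-scale lysate [intensity_table()]
#' @param fluid_table optional raw-scale fluid [intensity_table()]
#' @param interactions optional interaction data.frame
#' @param disease optional disease-association data.frame
#' @param out_dir optional output directory
#' @return a list of stage results plus `summary`, the headline counters
#' @export
run_pipeline <- function(secretome_table, params = secretome_params(),
                         annotations = NULL, sequences = NULL,
                         peptides = NULL, lysate_table = NULL,
                         fluid_table = NULL, interactions = NULL,
                         disease = NULL, out_dir = NULL) {
  res <- list()
  manifest <- character()
  summary <- list(n_input = nrow(secretome_table$values))

  filtered <- filter_by_replication(secretome_table, params$min_detected)
  summary$n_after_filter <- nrow(filtered$values)
  imputed <- impute_left_shifted(log_transform(filtered, 2),
                                 params$impute_shift, params$impute_width,
                                 params$seed)
  res$table <- imputed
  res$correlation <- pearson_matrix(imputed, use = "complete")
  summary$mean_within_group_correlation <- mean_within_group_cor(res$correlation,
                                                                 imputed$design)
  manifest <- c(manifest, "preprocess", "correlation")

  counts <- detection_counts(filtered)
  means <- group_means(imputed)
  res$counts <- counts
  res$cts_calls <- classify_specificity(counts, means, params)
  summary$n_cts <- sum(!is.na(res$cts_calls$specific_group))
  summary$n_uniquely_detected <-
    sum(!is.na(uniquely_detected(counts, params$min_detected)$unique_group))
  manifest <- c(manifest, "specificity")

  if (!is.null(lysate_table)) {
    lys_filtered <- filter_by_replication(lysate_table, 2L)
    lys_imputed <- impute_left_shifted(log_transform(lys_filtered, 2),
                                       params$impute_shift, params$impute_width,
                                       params$seed + 1L)
    res$lysate_calls <- lysate_specificity(lys_imputed, params)
    res$concordance <- concordance(res$cts_calls, res$lysate_calls)
    summary$n_expression_driven <-
      sum(res$concordance$calls$category == "expression_driven")
    summary$n_secretion_specific <-
      sum(res$concordance$calls$category == "secretion_specific")
    manifest <- c(manifest, "lysate", "concordance")
    if (!is.null(interactions) && !is.null(annotations)) {
      res$edges <- build_map(res$cts_calls, res$lysate_calls, interactions,
                             annotations)
      summary$n_edges <- nrow(res$edges)
      manifest <- c(manifest, "network")
    }
  }

  if (!is.null(annotations)) {
    groups <- design_groups(filtered$design)
    detected_by_group <- lapply(stats::setNames(groups, groups), function(g)
      rownames(counts$counts)[counts$counts[, g] >= params$min_detected])
    res$secretion <- classify_secretion(annotations, detected_by_group)
    summary$pct_shed_by_group <-
      stats::setNames(as.list(res$secretion$composition$pct_shed),
                      res$secretion$composition$group)
    manifest <- c(manifest, "secretion_class")
    if (!is.null(peptides)) {
      res$peptide_map <- map_peptides(peptides, annotations)
      summary$fraction_ectodomain <- res$peptide_map$summary$fraction_ectodomain
      summary$fraction_intracellular <- res$peptide_map$summary$fraction_intracellular
      manifest <- c(manifest, "topology")
      if (!is.null(sequences)) {
        res$cleavage <- call_cleavage(res$peptide_map$mapping, sequences)
        summary$n_semi_tryptic <- sum(res$cleavage$specificity == "semi_tryptic")
        manifest <- c(manifest, "cleavage")
      }
    }
  }

  if (!is.null(fluid_table)) {
    res$fluid_quartiles <- quartile_bin(fluid_table, min_detected = 3L)
    res$origin <- assign_origin(res$fluid_quartiles, counts, res$cts_calls,
                                annotations, params$min_detected)
    summary$n_fluid <- nrow(res$fluid_quartiles)
    summary$pct_fluid_in_resource <- 100 * mean(res$origin$origin$in_resource)
    manifest <- c(manifest, "fluid_mapping")
    if (!is.null(disease)) {
      res$disease <- join_disease(res$origin$origin, disease, params$ei_min,
                                  means)
      summary$n_disease_associations <- nrow(res$disease)
      manifest <- c(manifest, "disease")
    }
  }

  res$summary <- summary
  res$manifest <- manifest
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

mean_within_group_cor <- function(cm, design) {
  vals <- c()
  for (g in design_groups(design)) {
    ids <- design$sample_id[design$group == g]
    if (length(ids) < 2) next
    sub <- cm[ids, ids]
    vals <- c(vals, sub[upper.tri(sub)])
  }
  mean(vals)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_intensity_table(res$table, file.path(out_dir, "imputed_log2.tsv"))
  wt(res$cts_calls, "specificity_calls.tsv")
  if (!is.null(res$lysate_calls)) wt(res$lysate_calls, "lysate_calls.tsv")
  if (!is.null(res$concordance)) wt(res$concordance$calls, "concordance.tsv")
  if (!is.null(res$edges)) wt(res$edges, "edges.tsv")
  if (!is.null(res$fluid_quartiles)) wt(res$fluid_quartiles, "fluid_quartiles.tsv")
  if (!is.null(res$disease)) wt(res$disease, "disease.tsv")
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(res$manifest, file.path(out_dir, "MANIFEST"))
  invisible(out_dir)
}

#' Recompute headline counters from supplementary-style tables
#'
#' Given paths to resource-style tables (wide TSVs with intensity columns),
#' auto-maps columns by header inspection and recomputes the pipeline's
#' counting statistics: replicate-filter survivors for the secretome
#' resource (>= `min_detected` of the replicates of any cell type) and the
#' >= 3-of-4 counter for a CSF table. Files that cannot be mapped are
#' skipped with a reason.
#'
#' @param paths named list of file paths (names are free-form table labels)
#' @param params a [secretome_params()]
#' @return a data.frame `table`, `quantity`, `computed`, `note`
#' @export
reproduce_supplementary <- function(paths, params = secretome_params()) {
  rows <- list()
  add <- function(tab, qty, val, note = "")
    rows[[length(rows) + 1L]] <<- data.frame(table = tab, quantity = qty,
                                             computed = val, note = note,
                                             stringsAsFactors = FALSE)
  for (label in names(paths)) {
    path <- paths[[label]]
    if (!file.exists(path)) {
      add(label, "skipped", NA_real_, "file not found")
      next
    }
    hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    int_cols <- grep("^(LFQ [Ii]ntensity|[Ii]ntensity)[ ._]", hdr, value = TRUE)
    if (!length(int_cols))
      int_cols <- grep("_[0-9]+$", hdr, value = TRUE)
    if (length(int_cols) < 2L) {
      add(label, "skipped", NA_real_, "no intensity columns recognized")
      next
    }
    design <- design_from_headers(int_cols)
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                            na.strings = c("NA", "NaN", ""))
    id_col <- intersect(c("Protein IDs", "Majority protein IDs", "protein_id",
                          "Accession", "Uniprot"), names(df))[1]
    if (is.na(id_col)) id_col <- names(df)[1]
    vals <- as.matrix(df[, int_cols, drop = FALSE])
    mode(vals) <- "numeric"
    vals[!is.na(vals) & vals == 0] <- NA_real_
    ids <- make.unique(as.character(df[[id_col]]))
    dimnames(vals) <- list(ids, design$sample_id)
    tab <- intensity_table(vals, design, scale = "raw")
    counts <- detection_counts(tab)
    # n-1 of n replicates, capped at the configured bar (5/6 resource, 3/4 CSF)
    min_det <- min(params$min_detected, max(counts$totals) - 1L)
    n_keep <- sum(apply(counts$counts >= min_det, 1L, any))
    add(label, sprintf("proteins detected in >=%d replicates of any group", min_det),
        n_keep, sprintf("%d groups x %s replicates", length(counts$totals),
                        paste(unique(counts$totals), collapse = "/")))
  }
  do.call(rbind, rows)
}

# infer (group, replicate) from intensity column headers such as
# "LFQ intensity neuron_3" or "csf_2"
design_from_headers <- function(cols) {
  stripped <- sub("^(LFQ [Ii]ntensity|[Ii]ntensity)[ ._]", "", cols)
  m <- regmatches(stripped, regexec("^(.*?)[ ._]([0-9]+)$", stripped))
  ok <- vapply(m, length, integer(1)) == 3L
  group <- ifelse(ok, vapply(m, function(x) if (length(x) == 3) x[2] else "", character(1)),
                  stripped)
  repl <- ifelse(ok, as.integer(vapply(m, function(x) if (length(x) == 3) x[3] else "0",
                                       character(1))), NA_integer_)
  for (g in unique(group[is.na(repl)]))
    repl[is.na(repl) & group == g] <- seq_len(sum(is.na(repl) & group == g))
  sample_design(cols, group, repl)
}
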