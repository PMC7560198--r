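# Quartile dynamic-range binning of fluid/tissue proteomes and mapping of
# their proteins to cell-type origin via the secretome resource.

#' Quartile binning by abundance
#'
#' Ranks fluid proteins by abundance (mean of the present log10 LFQ values;
#' no imputation enters the ranking) and splits them into four bins:
#' quartile 1 holds the 25% most abundant proteins. Bin sizes are
#' `floor(n/4)` with the remainder given to the earlier bins, so sizes
#' differ by at most one and sum to n (n = 10 gives 3, 3, 2, 2). Ties are
#' broken by accession in lexicographic order, making the binning
#' deterministic. The table should already be detection-filtered (the CSF
#' convention is at least 3 of 4 replicates).
#'
#' @param fluid_table a raw-scale [intensity_table()]
#' @param min_detected replicate bar applied before binning (default 3);
#'   use 0 to skip
#' @return a data.frame `protein_id`, `abundance` (mean log10 LFQ),
#'   `quartile`
#' @export
quartile_bin <- function(fluid_table, min_detected = 3L) {
  if (fluid_table$scale != "raw")
    stop("quartile_bin expects a raw-scale table")
  tab <- if (min_detected > 0L)
    filter_by_replication(fluid_table, min_detected, scope = "any_group")
  else fluid_table
  vals <- log10(tab$values)
  abundance <- rowMeans(vals, na.rm = TRUE)
  ids <- rownames(tab$values)
  n <- length(ids)
  if (n == 0L) stop("no proteins left after filtering")
  ord <- order(-abundance, ids)      # descending abundance, ties by accession
  sizes <- rep(n %/% 4L, 4L)
  rem <- n %% 4L
  if (rem) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  if (n < 4L) {
    warning("fewer than 4 proteins; single bin")
    q <- rep(1L, n)
  } else {
    q <- rep(1:4, times = sizes)
  }
  quart <- integer(n)
  quart[ord] <- q
  data.frame(protein_id = ids, abundance = abundance, quartile = quart,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Map fluid proteins to their cell types of origin
#'
#' Looks each fluid protein up in the secretome resource: `in_resource` is
#' membership in the resource table, `source_groups` are the cell types
#' where the resource detects the protein in at least `min_detected`
#' replicates, and `cts_group` is the cell-type-specific secretion call if
#' one exists. Per quartile, the composition gives the percentage of
#' in-resource proteins whose sources include each cell type (a protein
#' contributes to every one of its source groups, so bars can exceed 100%).
#'
#' @param fluid_quartiles data.frame from [quartile_bin()]
#' @param resource_counts a [detection_counts()] object for the resource
#' @param cts_calls a `specificity_calls` data.frame
#'   (see [classify_specificity()]), or NULL
#' @param annotations optional annotation data.frame; with
#'   `glyco_only = TRUE` restricts the fluid proteins to glycoproteins
#' @param min_detected resource detection bar per cell type (default 5)
#' @param glyco_only restrict to glycoprotein-annotated fluid proteins
#' @return a list: `origin`, a data.frame with `in_resource`,
#'   `source_groups` (list column) and `cts_group`; `composition`, a
#'   quartile x cell-type percentage matrix; `cts_by_quartile`, the
#'   cell-type-specific proteins in each quartile
#' @export
assign_origin <- function(fluid_quartiles, resource_counts, cts_calls = NULL,
                          annotations = NULL, min_detected = 5L,
                          glyco_only = FALSE) {
  fq <- fluid_quartiles
  if (glyco_only) {
    if (is.null(annotations)) stop("glyco_only requires annotations")
    glyco <- annotations$protein_id[has_keyword(annotations, "glycoprotein")]
    fq <- fq[fq$protein_id %in% glyco, , drop = FALSE]
  }
  cm <- resource_counts$counts
  groups <- colnames(cm)
  in_resource <- fq$protein_id %in% rownames(cm)
  source_groups <- lapply(seq_len(nrow(fq)), function(i) {
    if (!in_resource[i]) return(character())
    groups[cm[fq$protein_id[i], ] >= min_detected]
  })
  cts <- rep(NA_character_, nrow(fq))
  if (!is.null(cts_calls)) {
    m <- match(fq$protein_id, cts_calls$protein_id)
    cts <- cts_calls$specific_group[m]
  }
  origin <- fq
  origin$in_resource <- in_resource
  origin$source_groups <- source_groups
  origin$cts_group <- cts
  quartiles <- sort(unique(fq$quartile))
  composition <- t(vapply(quartiles, function(q) {
    sel <- origin$quartile == q & origin$in_resource
    denom <- sum(sel)
    vapply(groups, function(g)
      if (denom) 100 * sum(vapply(origin$source_groups[sel],
                                  function(sg) g %in% sg, logical(1))) / denom
      else NA_real_,
      numeric(1))
  }, numeric(length(groups))))
  rownames(composition) <- paste0("Q", quartiles)
  cts_by_quartile <- lapply(stats::setNames(quartiles, paste0("Q", quartiles)),
                            function(q)
                              origin$protein_id[origin$quartile == q & !is.na(origin$cts_group)])
  list(origin = origin, composition = composition,
       cts_by_quartile = cts_by_quartile)
}

#' Join disease associations onto origin-mapped proteins
#'
#' Keeps gene-disease associations with evidence index at least `ei_min`
#' (default 0.9) and annotates each retained protein with its cell type of
#' specific secretion and, when group means are supplied, its relative
#' secretion level per cell type (linear group mean divided by the maximum
#' group mean).
#'
#' @param origin the `origin` data.frame from [assign_origin()]
#' @param disease data.frame from [read_disease()]
#' @param ei_min evidence-index cutoff (default 0.9)
#' @param log2_means optional matrix of per-group log2 means
#'   (see [group_means()])
#' @return a data.frame, one row per retained protein-disease pair, with
#'   `rel_<group>` columns when means are given
#' @export
join_disease <- function(origin, disease, ei_min = 0.9, log2_means = NULL) {
  keep <- disease[disease$evidence_index >= ei_min, , drop = FALSE]
  m <- match(keep$protein_id, origin$protein_id)
  out <- data.frame(protein_id = keep$protein_id, disease = keep$disease,
                    evidence_index = keep$evidence_index,
                    quartile = origin$quartile[m],
                    cts_group = origin$cts_group[m],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(log2_means)) {
    lin <- 2 ^ log2_means
    rel <- lin / apply(lin, 1L, max)
    mm <- match(out$protein_id, rownames(rel))
    for (g in colnames(rel)) out[[paste0("rel_", g)]] <- rel[mm, g]
  }
  out
}
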