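#' Cell-type-resolved ligand-receptor interaction map
#'
#' Joins cell-type-specifically secreted proteins to their binary
#' interaction partners: a directed edge ligand -> receptor is emitted when
#' the ligand has a cell-type-specific secretion call, the pair occurs in
#' the interaction table (either order), the receptor is lysate-specific to
#' some cell type (2.5-fold rule) and the receptor carries a
#' membrane/transmembrane annotation. Self-group edges (autocrine) are
#' allowed; when both partners qualify in both directions two directed
#' edges result. Isoform suffixes (`P12345-2`) are stripped before joining
#' so secretome and lysate accessions align.
#'
#' @param cts_calls a `specificity_calls` data.frame
#'   (see [classify_specificity()])
#' @param lysate_calls data.frame from [lysate_specificity()]
#' @param interactions data.frame from [read_interactions()]
#' @param annotations annotation data.frame (see [read_annotations()])
#' @return a data.frame of edges: `ligand`, `ligand_group`, `receptor`,
#'   `receptor_group`, `source`, sorted for deterministic output
#' @export
build_map <- function(cts_calls, lysate_calls, interactions, annotations) {
  strip <- function(x) sub("-[0-9]+$", "", x)
  lig_group <- stats::setNames(cts_calls$specific_group, strip(cts_calls$protein_id))
  lig_group <- lig_group[!is.na(lig_group)]
  rec_group <- stats::setNames(lysate_calls$lysate_group, strip(lysate_calls$protein_id))
  rec_group <- rec_group[!is.na(rec_group)]
  membrane <- strip(annotations$protein_id)[
    has_keyword(annotations, "membrane") |
      has_keyword(annotations, "transmembrane_single_pass")]
  edges <- list()
  add_edge <- function(a, b, src) {
    if (a %in% names(lig_group) && b %in% names(rec_group) && b %in% membrane)
      edges[[length(edges) + 1L]] <<- data.frame(
        ligand = a, ligand_group = unname(lig_group[a]),
        receptor = b, receptor_group = unname(rec_group[b]),
        source = src, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(interactions))) {
    a <- strip(interactions$a[i]); b <- strip(interactions$b[i])
    add_edge(a, b, interactions$source[i])
    add_edge(b, a, interactions$source[i])
  }
  if (!length(edges))
    return(data.frame(ligand = character(), ligand_group = character(),
                      receptor = character(), receptor_group = character(),
                      source = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, edges)
  out <- out[!duplicated(paste(out$ligand, out$receptor)), , drop = FALSE]
  out <- out[order(out$ligand, out$receptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}
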