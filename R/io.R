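#' Read a protein-group LFQ table
#'
#' Ingests a tab-separated protein-group table and binds its intensity
#' columns to a [sample_design()]. Two dialects are supported:
#' \describe{
#'   \item{`"plain"`}{a `protein_id` (or first) column plus one column per
#'     sample named exactly as in the design.}
#'   \item{`"maxquant"`}{MaxQuant `proteinGroups.txt` conventions: protein
#'     ids in `Protein IDs`, intensities in `LFQ intensity <sample>` columns,
#'     and rows flagged `+` in `Reverse`, `Potential contaminant` (or
#'     `Contaminant`) or `Only identified by site` dropped.}
#' }
#' Zeros, empty cells and `NaN` text all denote missing values (MaxQuant
#' writes 0 for non-quantified proteins); they become `NA`, never 0, so the
#' raw-scale invariant "all present values > 0" holds after ingestion. The
#' first accession of a semicolon-separated protein-group id is the row key;
#' the full list is kept in the `protein_groups` attribute. A load report
#' (rows read / dropped per reason) is attached as attribute `report` and
#' emitted with `message()`.
#'
#' @param path TSV file
#' @param design a [sample_design()]
#' @param dialect `"plain"` or `"maxquant"`
#' @return a raw-scale [intensity_table()]
#' @export
read_protein_groups <- function(path, design, dialect = c("plain", "maxquant")) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", "NaN", ""))
  n_read <- nrow(df)
  dropped <- c(reverse = 0L, contaminant = 0L, site_only = 0L)
  if (dialect == "maxquant") {
    flag <- function(col) if (col %in% names(df)) !is.na(df[[col]]) & df[[col]] == "+" else rep(FALSE, nrow(df))
    rv <- flag("Reverse")
    ct <- flag("Potential contaminant") | flag("Contaminant")
    so <- flag("Only identified by site")
    dropped <- c(reverse = sum(rv), contaminant = sum(ct & !rv),
                 site_only = sum(so & !rv & !ct))
    df <- df[!(rv | ct | so), , drop = FALSE]
    id_col <- intersect(c("Protein IDs", "Majority protein IDs", "protein_id"), names(df))[1]
    if (is.na(id_col)) stop("no protein-id column found in maxquant dialect file")
    want <- paste("LFQ intensity", design$sample_id)
  } else {
    id_col <- if ("protein_id" %in% names(df)) "protein_id" else names(df)[1]
    want <- design$sample_id
  }
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols))
    stop("missing sample column(s): ", paste(missing_cols, collapse = ", "))
  groups_full <- as.character(df[[id_col]])
  ids <- vapply(strsplit(groups_full, ";", fixed = TRUE), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate protein ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, want, drop = FALSE])
  mode(vals) <- "numeric"
  vals[!is.na(vals) & vals == 0] <- NA_real_
  dimnames(vals) <- list(ids, design$sample_id)
  tab <- intensity_table(vals, design, scale = "raw")
  report <- list(rows_read = n_read, rows_kept = nrow(vals), dropped = as.list(dropped))
  message(sprintf("read_protein_groups: %d rows read, %d kept (dropped: reverse %d, contaminant %d, site-only %d)",
                  n_read, nrow(vals), dropped[["reverse"]], dropped[["contaminant"]],
                  dropped[["site_only"]]))
  attr(tab, "protein_groups") <- stats::setNames(groups_full, ids)
  attr(tab, "report") <- report
  tab
}

#' Read a peptide table
#'
#' TSV with columns `protein_id`, `sequence`, `start`, `end`, `aa_before`,
#' `aa_after` (1-based inclusive coordinates; `-` marks a protein terminus).
#' Rows whose coordinates are inconsistent with the sequence length
#' (`end - start + 1 != nchar(sequence)` or `start < 1`) are rejected with a
#' counted warning.
#'
#' @param path TSV file
#' @return a `data.frame` of valid peptide records; the number of rejected
#'   rows is attached as attribute `rejected`
#' @export
read_peptides <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "sequence", "start", "end", "aa_before", "aa_after")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("peptide table lacks column(s): ", paste(missing_cols, collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  ok <- !is.na(df$start) & !is.na(df$end) & df$start >= 1L &
    (df$end - df$start + 1L) == nchar(df$sequence)
  if (any(!ok))
    warning(sum(!ok), " peptide row(s) rejected (start/end inconsistent with sequence length)")
  out <- df[ok, need, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- sum(!ok)
  out
}

#' Write a peptide table
#' @param peptides data.frame as returned by [read_peptides()]
#' @param path output TSV
#' @export
write_peptides <- function(peptides, path) {
  utils::write.table(peptides, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

parse_topology <- function(txt) {
  # "extracellular:1-150;transmembrane:151-171;intracellular:172-300"
  if (is.na(txt) || !nzchar(txt)) return(data.frame(kind = character(),
                                                    start = integer(), end = integer()))
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([a-z_]+):([0-9]+)-([0-9]+)$", parts))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed topology segment: ", parts[bad][1])
  data.frame(kind = vapply(m, `[`, character(1), 2L),
             start = as.integer(vapply(m, `[`, character(1), 3L)),
             end = as.integer(vapply(m, `[`, character(1), 4L)),
             stringsAsFactors = FALSE)
}

format_topology <- function(seg) {
  if (!nrow(seg)) return("")
  paste(sprintf("%s:%d-%d", seg$kind, seg$start, seg$end), collapse = ";")
}

known_keywords <- c("secreted", "membrane", "transmembrane_single_pass",
                    "gpi_anchor", "glycoprotein", "cytoplasm", "nucleus",
                    "extracellular_matrix")

#' Read a protein annotation table
#'
#' TSV with columns `protein_id`, `keywords` (semicolon-separated),
#' `topology` (semicolon-separated `kind:start-end` segments, 1-based
#' inclusive) and `sequence_length`. Keywords outside the controlled
#' vocabulary are preserved but ignored by the classifiers. Records with
#' overlapping topology segments, segments outside `1..sequence_length`, or a
#' `transmembrane_single_pass` keyword without exactly one transmembrane
#' segment are rejected with a counted warning.
#'
#' @param path TSV file
#' @return a `data.frame` with list-columns `keywords` and `topology`
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("protein_id", "keywords", "topology", "sequence_length")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("annotation table lacks column(s): ", paste(missing_cols, collapse = ", "))
  kw <- lapply(df$keywords, function(s)
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1]])
  topo <- lapply(ifelse(is.na(df$topology), "", df$topology), parse_topology)
  len <- as.integer(df$sequence_length)
  ok <- vapply(seq_len(nrow(df)), function(i)
    validate_annotation(kw[[i]], topo[[i]], len[i]), logical(1))
  if (any(!ok))
    warning(sum(!ok), " annotation record(s) rejected (topology/keyword invariant violated)")
  out <- data.frame(protein_id = df$protein_id[ok], sequence_length = len[ok],
                    stringsAsFactors = FALSE)
  out$keywords <- kw[ok]
  out$topology <- topo[ok]
  rownames(out) <- NULL
  attr(out, "rejected") <- sum(!ok)
  out
}

validate_annotation <- function(keywords, topology, sequence_length) {
  if (is.na(sequence_length) || sequence_length < 1) return(FALSE)
  if (nrow(topology)) {
    if (any(topology$start < 1 | topology$end > sequence_length |
            topology$start > topology$end)) return(FALSE)
    o <- order(topology$start)
    s <- topology$start[o]; e <- topology$end[o]
    if (nrow(topology) > 1 && any(s[-1] <= e[-nrow(topology)])) return(FALSE)
  }
  if ("transmembrane_single_pass" %in% keywords &&
      sum(topology$kind == "transmembrane") != 1L) return(FALSE)
  TRUE
}

#' Write a protein annotation table
#' @param annotations data.frame as returned by [read_annotations()]
#' @param path output TSV
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(protein_id = annotations$protein_id,
                   keywords = vapply(annotations$keywords, paste, character(1), collapse = ";"),
                   topology = vapply(annotations$topology, format_topology, character(1)),
                   sequence_length = annotations$sequence_length,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary protein-protein interaction table
#'
#' TSV with columns `a`, `b` and optionally `source`. Self-pairs are dropped
#' and pairs de-duplicated regardless of order (the first source tag wins).
#'
#' @param path TSV file
#' @return a `data.frame` with columns `a`, `b`, `source`
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("a", "b") %in% names(df)))
    stop("interaction table needs columns a, b")
  if (is.null(df$source)) df$source <- "unknown"
  df <- df[df$a != df$b, , drop = FALSE]
  lo <- pmin(df$a, df$b); hi <- pmax(df$a, df$b)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  out <- data.frame(a = lo[keep], b = hi[keep], source = df$source[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a gene-disease association table
#'
#' TSV with columns `protein_id`, `disease`, `evidence_index`; the evidence
#' index must lie in [0, 1] (rows outside are rejected with a warning).
#'
#' @param path TSV file
#' @return a `data.frame`
#' @export
read_disease <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "disease", "evidence_index")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("disease table lacks column(s): ", paste(missing_cols, collapse = ", "))
  df$evidence_index <- as.numeric(df$evidence_index)
  ok <- !is.na(df$evidence_index) & df$evidence_index >= 0 & df$evidence_index <= 1
  if (any(!ok)) warning(sum(!ok), " disease row(s) rejected (evidence index outside [0,1])")
  out <- df[ok, need, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read protein sequences from FASTA
#' @param path FASTA file
#' @return named character vector of amino-acid sequences (first token of
#'   each header is the name)
#' @export
read_protein_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Write protein sequences as FASTA
#' @param sequences named character vector
#' @param path output file
#' @export
write_protein_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}
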