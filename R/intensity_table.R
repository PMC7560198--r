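#' Protein-by-sample intensity table
#'
#' The central container of the pipeline: a numeric matrix of LFQ (or
#' log-transformed) intensities with proteins in rows and samples in
#' columns, a [sample_design()] binding columns to groups, and an explicit
#' missing-value state (`NA`). Two logical matrices travel with the values:
#' `detected` records which cells held a genuine measurement at ingestion
#' time (the pre-imputation mask used for all detection counting) and
#' `imputed` marks cells later filled by [impute_left_shifted()].
#'
#' @param values numeric matrix; rownames are protein accessions
#' @param design a [sample_design()]; `design$sample_id` must match `colnames(values)`
#' @param scale one of `"raw"`, `"log2"`, `"log10"`
#' @param detected logical matrix of genuine measurements; defaults to `!is.na(values)`
#' @param imputed logical matrix of imputed cells; defaults to all-`FALSE`
#' @return an object of class `intensity_table`
#' @export
intensity_table <- function(values, design, scale = c("raw", "log2", "log10"),
                            detected = NULL, imputed = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must carry protein accessions as rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (!inherits(design, "sample_design")) design <- as_sample_design(design)
  if (is.null(colnames(values))) colnames(values) <- design$sample_id
  if (!identical(colnames(values), design$sample_id))
    stop("column names of values must equal design$sample_id, in order")
  if (scale == "raw" && any(values <= 0, na.rm = TRUE))
    stop("raw-scale intensities must be positive; encode missing as NA, not 0")
  if (is.null(detected)) detected <- !is.na(values)
  if (is.null(imputed)) imputed <- matrix(FALSE, nrow(values), ncol(values),
                                          dimnames = dimnames(values))
  stopifnot(identical(dim(detected), dim(values)),
            identical(dim(imputed), dim(values)))
  structure(list(values = values, design = design, scale = scale,
                 detected = detected, imputed = imputed),
            class = "intensity_table")
}

as_sample_design <- function(df) {
  sample_design(df$sample_id, df$group, df$replicate)
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf("intensity_table: %d proteins x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  groups: %s\n", paste(design_groups(x$design), collapse = ", ")))
  cat(sprintf("  missing: %d cells; imputed: %d cells\n",
              sum(is.na(x$values)), sum(x$imputed)))
  invisible(x)
}

#' @export
dim.intensity_table <- function(x) dim(x$values)

#' Protein accessions of an intensity table
#' @param table an `intensity_table`
#' @return character vector
#' @export
protein_ids <- function(table) rownames(table$values)

#' Subset an intensity table by protein
#' @param table an `intensity_table`
#' @param keep logical or character or integer index over proteins
#' @return an `intensity_table`
#' @export
subset_proteins <- function(table, keep) {
  intensity_table(table$values[keep, , drop = FALSE], table$design, table$scale,
                  detected = table$detected[keep, , drop = FALSE],
                  imputed = table$imputed[keep, , drop = FALSE])
}

#' Write an intensity table as plain TSV
#'
#' One `protein_id` column plus one column per sample. Missing cells are
#' written empty; values are written with full precision so a write/read
#' round trip is bit-identical.
#'
#' @param table an `intensity_table`
#' @param path output TSV path
#' @export
write_intensity_table <- function(table, path) {
  vals <- table$values
  chr <- matrix("", nrow(vals), ncol(vals))
  present <- !is.na(vals)
  chr[present] <- sprintf("%.17g", vals[present])
  df <- data.frame(protein_id = rownames(vals), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("protein_id", colnames(vals))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
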