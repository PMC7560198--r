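#' Experimental sample design
#'
#' Binds each sample column to a biological group (cell type or condition)
#' and a replicate number. Sample ids must be unique and replicate numbers
#' unique within each group.
#'
#' @param sample_id character vector of sample labels
#' @param group character vector of group names, recycled if length 1
#' @param replicate positive integer replicate numbers
#' @return a `data.frame` of class `sample_design`
#' @export
sample_design <- function(sample_id, group, replicate) {
  sample_id <- as.character(sample_id)
  group <- rep_len(as.character(group), length(sample_id))
  replicate <- as.integer(replicate)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ", paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (any(replicate < 1L)) stop("replicate numbers must be positive")
  if (length(replicate) != length(sample_id)) stop("replicate length mismatch")
  key <- paste(group, replicate)
  if (anyDuplicated(key))
    stop("replicate numbers must be unique within each group")
  structure(data.frame(sample_id = sample_id, group = group,
                       replicate = replicate, stringsAsFactors = FALSE),
            class = c("sample_design", "data.frame"))
}

#' Read a sample design from YAML
#'
#' Expects a mapping `sample_id: {group: ..., replicate: ...}`.
#'
#' @param path YAML file
#' @return a `sample_design`
#' @export
read_design <- function(path) {
  y <- yaml::read_yaml(path)
  if (!length(y)) stop("empty design file: ", path)
  sample_design(names(y),
                vapply(y, function(e) as.character(e$group), character(1)),
                vapply(y, function(e) as.integer(e$replicate), integer(1)))
}

#' Write a sample design as YAML
#' @param design a `sample_design`
#' @param path output file
#' @export
write_design <- function(design, path) {
  y <- lapply(seq_len(nrow(design)), function(i)
    list(group = design$group[i], replicate = design$replicate[i]))
  names(y) <- design$sample_id
  yaml::write_yaml(y, path)
  invisible(path)
}

design_groups <- function(design) unique(design$group)

samples_of <- function(design, group) design$sample_id[design$group == group]
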