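# Independent brute-force reimplementations used as oracles. These are kept
# deliberately naive (explicit loops, no shared code with the package
# internals beyond the public data layout).

oracle_detection_counts <- function(table) {
  groups <- unique(table$design$group)
  out <- matrix(0L, nrow(table$values), length(groups),
                dimnames = list(rownames(table$values), groups))
  for (i in seq_len(nrow(table$values)))
    for (g in groups)
      for (j in which(table$design$group == g))
        if (table$detected[i, j]) out[i, g] <- out[i, g] + 1L
  out
}

oracle_classify <- function(counts_mat, means_mat, min_detected = 5,
                            max_other = 2, fold = 5) {
  groups <- colnames(counts_mat)
  grp <- rep(NA_character_, nrow(counts_mat))
  for (i in seq_len(nrow(counts_mat))) {
    winners <- c()
    for (g in groups) {
      if (counts_mat[i, g] < min_detected) next
      rule1 <- TRUE; rule2 <- TRUE
      for (h in setdiff(groups, g)) {
        if (counts_mat[i, h] > max_other) rule1 <- FALSE
        if (means_mat[i, g] - means_mat[i, h] < log2(fold)) rule2 <- FALSE
      }
      if (rule1 || rule2) winners <- c(winners, g)
    }
    if (length(winners) == 1) grp[i] <- winners
  }
  grp
}

oracle_map_region <- function(s, e, topo) {
  pos <- s:e
  in_kind <- function(kind) {
    hit <- rep(FALSE, length(pos))
    for (k in which(topo$kind == kind))
      hit <- hit | (pos >= topo$start[k] & pos <= topo$end[k])
    hit
  }
  if (any(in_kind("transmembrane"))) return("transmembrane_spanning")
  if (all(in_kind("extracellular"))) return("ectodomain")
  if (all(in_kind("intracellular"))) return("intracellular")
  "unresolved"
}

oracle_quartile <- function(ids, abundance) {
  ord <- order(-abundance, ids)
  n <- length(ids)
  sizes <- c(ceiling(n / 4))
  r <- n - sizes
  sizes <- c(sizes, ceiling(r / 3)); r <- n - sum(sizes)
  sizes <- c(sizes, ceiling(r / 2)); r <- n - sum(sizes)
  sizes <- c(sizes, r)
  q <- integer(n)
  q[ord] <- rep(1:4, times = sizes)
  q
}

oracle_build_map <- function(cts_calls, lysate_calls, interactions, annotations) {
  strip <- function(x) sub("-[0-9]+$", "", x)
  is_membrane <- function(pid) {
    i <- match(pid, strip(annotations$protein_id))
    !is.na(i) && any(c("membrane", "transmembrane_single_pass") %in%
                       annotations$keywords[[i]])
  }
  cts <- cts_calls[!is.na(cts_calls$specific_group), ]
  lys <- lysate_calls[!is.na(lysate_calls$lysate_group), ]
  edges <- data.frame(ligand = character(), receptor = character(),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(interactions))) {
    pair <- strip(c(interactions$a[i], interactions$b[i]))
    for (dir in list(pair, rev(pair))) {
      a <- dir[1]; b <- dir[2]
      if (a %in% strip(cts$protein_id) && b %in% strip(lys$protein_id) &&
          is_membrane(b))
        edges <- rbind(edges, data.frame(ligand = a, receptor = b,
                                         stringsAsFactors = FALSE))
    }
  }
  unique(edges[order(edges$ligand, edges$receptor), , drop = FALSE])
}

# quick builder for small intensity tables
toy_table <- function(values, groups, scale = "raw") {
  n_rep <- ncol(values) / length(groups)
  design <- sample_design(paste(rep(groups, each = n_rep),
                                rep(seq_len(n_rep), length(groups)), sep = "_"),
                          rep(groups, each = n_rep),
                          rep(seq_len(n_rep), length(groups)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  colnames(values) <- design$sample_id
  intensity_table(values, design, scale = scale)
}
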