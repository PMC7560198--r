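# Peptide-to-topology mapping, shed-vs-soluble classification, and
# tryptic-specificity / cleavage-site calling. Coordinates are 1-based
# inclusive throughout (UniProt convention).

annotation_index <- function(annotations) {
  stats::setNames(seq_len(nrow(annotations)), annotations$protein_id)
}

has_keyword <- function(annotations, kw) {
  vapply(annotations$keywords, function(k) kw %in% k, logical(1))
}

#' Map peptides onto membrane-protein topology
#'
#' Quality control for a shedding-dominated secretome: peptides of
#' single-pass transmembrane proteins are assigned to the protein region
#' they fall in. A peptide overlapping the transmembrane segment is
#' `transmembrane_spanning` (this takes precedence, keeping the ectodomain
#' fraction strict); one lying entirely within extracellular segments
#' (signal peptide excluded) is `ectodomain`; entirely within intracellular
#' segments is `intracellular`; anything else — peptides of proteins
#' without usable topology, peptides of multi-pass or non-TM proteins,
#' coordinates beyond the sequence, or peptides straddling unannotated
#' residues — is `unresolved`. Type-II orientation is honored: "ectodomain"
#' means the extracellular-annotated segments wherever they lie.
#'
#' @param peptides peptide data.frame (see [read_peptides()])
#' @param annotations annotation data.frame (see [read_annotations()])
#' @return a list: `mapping`, the peptide table with a `region` column; and
#'   `summary`, the fractions of ectodomain / transmembrane-spanning /
#'   intracellular peptides among resolved ones plus the resolved count
#' @export
map_peptides <- function(peptides, annotations) {
  idx <- annotation_index(annotations)
  single_tm <- has_keyword(annotations, "transmembrane_single_pass")
  region <- character(nrow(peptides))
  overflow <- 0L
  for (i in seq_len(nrow(peptides))) {
    j <- idx[peptides$protein_id[i]]
    if (is.na(j) || !single_tm[j] || !nrow(annotations$topology[[j]])) {
      region[i] <- "unresolved"; next
    }
    topo <- annotations$topology[[j]]
    s <- peptides$start[i]; e <- peptides$end[i]
    if (e > annotations$sequence_length[j]) {
      region[i] <- "unresolved"; overflow <- overflow + 1L; next
    }
    region[i] <- classify_region(s, e, topo)
  }
  if (overflow) warning(overflow, " peptide(s) extend beyond the protein sequence; unresolved")
  mapping <- peptides
  mapping$region <- region
  resolved <- region[region != "unresolved"]
  summary <- list(
    n_resolved = length(resolved),
    fraction_ectodomain = mean(resolved == "ectodomain"),
    fraction_transmembrane = mean(resolved == "transmembrane_spanning"),
    fraction_intracellular = mean(resolved == "intracellular"))
  list(mapping = mapping, summary = summary)
}

classify_region <- function(s, e, topo) {
  covered_by <- function(kind) {
    seg <- topo[topo$kind == kind, , drop = FALSE]
    if (!nrow(seg)) return(FALSE)
    pos <- s:e
    all(vapply(pos, function(p) any(p >= seg$start & p <= seg$end), logical(1)))
  }
  tm <- topo[topo$kind == "transmembrane", , drop = FALSE]
  if (nrow(tm) && any(s <= tm$end & e >= tm$start)) return("transmembrane_spanning")
  if (covered_by("extracellular")) return("ectodomain")
  if (covered_by("intracellular")) return("intracellular")
  "unresolved"
}

#' Shed-vs-soluble secretion classification
#'
#' Splits secretome proteins into proteolytically released membrane-protein
#' ectodomains and classically secreted soluble proteins:
#' `shed_membrane` for proteins annotated single-pass transmembrane or
#' GPI-anchored, `soluble_secreted` for proteins with the secreted keyword
#' and no membrane anchoring, `other` for the rest.
#'
#' @param annotations annotation data.frame (see [read_annotations()])
#' @param detected_by_group optional named list, group name -> character
#'   vector of detected protein ids; when given, per-group shed/soluble
#'   counts and percentages are computed
#' @param glyco_only when counting per group, restrict to proteins with the
#'   glycoprotein keyword (default TRUE, the convention for the
#'   glyco-enriched secretome counts)
#' @return a list: `classes`, data.frame `protein_id`, `class`; and, when
#'   `detected_by_group` is given, `composition`, a per-group data.frame of
#'   shed/soluble counts and percentages
#' @export
classify_secretion <- function(annotations, detected_by_group = NULL,
                               glyco_only = TRUE) {
  shed <- has_keyword(annotations, "transmembrane_single_pass") |
    has_keyword(annotations, "gpi_anchor")
  soluble <- has_keyword(annotations, "secreted") & !shed
  cls <- ifelse(shed, "shed_membrane", ifelse(soluble, "soluble_secreted", "other"))
  classes <- data.frame(protein_id = annotations$protein_id, class = cls,
                        stringsAsFactors = FALSE, row.names = NULL)
  out <- list(classes = classes)
  if (!is.null(detected_by_group)) {
    glyco <- annotations$protein_id[has_keyword(annotations, "glycoprotein")]
    comp <- do.call(rbind, lapply(names(detected_by_group), function(g) {
      ids <- detected_by_group[[g]]
      if (glyco_only) ids <- intersect(ids, glyco)
      k <- cls[match(ids, annotations$protein_id)]
      n_shed <- sum(k == "shed_membrane", na.rm = TRUE)
      n_sol <- sum(k == "soluble_secreted", na.rm = TRUE)
      denom <- n_shed + n_sol
      data.frame(group = g, n_shed = n_shed, n_soluble = n_sol,
                 pct_shed = if (denom) 100 * n_shed / denom else NA_real_,
                 pct_soluble = if (denom) 100 * n_sol / denom else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    out$composition <- comp
  }
  out
}

#' Tryptic specificity and cleavage-site calling
#'
#' Decides, for each peptide, whether its termini are consistent with
#' trypsin (cleavage after K or R; the proline exception is ignored by
#' default, matching common search-engine settings, and can be enabled).
#' A terminus is tryptic when the residue preceding the cut is K/R or the
#' terminus coincides with the protein's natural terminus. Peptides with
#' exactly one non-tryptic terminus are `semi_tryptic` and nominate an
#' endogenous protease cleavage position: the residue preceding the peptide
#' for an N-terminal non-specificity, the peptide's last residue for a
#' C-terminal one. Flanking residues are checked against the sequence; a
#' mismatch is a hard error.
#'
#' @param peptides peptide data.frame (see [read_peptides()])
#' @param sequences named character vector of protein sequences
#' @param proline_rule if TRUE, a cut followed by proline is not tryptic
#' @return the peptide table with columns `n_term_tryptic`,
#'   `c_term_tryptic`, `specificity` (`tryptic`, `semi_tryptic`,
#'   `non_tryptic`) and `cleavage_position` (`NA` unless semi-tryptic)
#' @export
call_cleavage <- function(peptides, sequences, proline_rule = FALSE) {
  n <- nrow(peptides)
  n_tryp <- logical(n); c_tryp <- logical(n); cleave <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    seq <- sequences[[peptides$protein_id[i]]]
    if (is.null(seq) || is.na(seq))
      stop("no sequence for protein ", peptides$protein_id[i])
    s <- peptides$start[i]; e <- peptides$end[i]
    len <- nchar(seq)
    if (e > len) stop("peptide beyond sequence end for ", peptides$protein_id[i])
    if (substr(seq, s, e) != peptides$sequence[i])
      stop("peptide sequence mismatch at ", peptides$protein_id[i], ":", s)
    before <- if (s == 1L) "-" else substr(seq, s - 1L, s - 1L)
    after <- if (e == len) "-" else substr(seq, e + 1L, e + 1L)
    if (peptides$aa_before[i] != before)
      stop("aa_before mismatch for ", peptides$protein_id[i], ":", s,
           " (table ", peptides$aa_before[i], ", sequence ", before, ")")
    if (peptides$aa_after[i] != after)
      stop("aa_after mismatch for ", peptides$protein_id[i], ":", e,
           " (table ", peptides$aa_after[i], ", sequence ", after, ")")
    first <- substr(peptides$sequence[i], 1L, 1L)
    last <- substr(peptides$sequence[i], e - s + 1L, e - s + 1L)
    nt <- s == 1L || (before %in% c("K", "R") && !(proline_rule && first == "P"))
    ct <- e == len || (last %in% c("K", "R") && !(proline_rule && after == "P"))
    n_tryp[i] <- nt; c_tryp[i] <- ct
    if (xor(nt, ct)) cleave[i] <- if (!nt) s - 1L else e
  }
  out <- peptides
  out$n_term_tryptic <- n_tryp
  out$c_term_tryptic <- c_tryp
  out$specificity <- ifelse(n_tryp & c_tryp, "tryptic",
                            ifelse(n_tryp | c_tryp, "semi_tryptic", "non_tryptic"))
  out$cleavage_position <- cleave
  out
}

#' In-silico tryptic digest
#'
#' Cuts a protein sequence after every K/R (the proline exception is
#' optional) and emits all peptides with up to `missed` missed cleavages
#' within the given length bounds, with 1-based inclusive coordinates and
#' flanking residues (`-` at protein termini).
#'
#' @param sequence amino-acid string
#' @param protein_id accession attached to the records
#' @param missed maximum missed cleavages (default 2)
#' @param min_len,max_len peptide length bounds (defaults 6 and 30)
#' @param proline_rule if TRUE, do not cut before proline
#' @return a peptide data.frame in [read_peptides()] layout
#' @export
tryptic_digest <- function(sequence, protein_id, missed = 2L,
                           min_len = 6L, max_len = 30L, proline_rule = FALSE) {
  len <- nchar(sequence)
  res <- strsplit(sequence, "")[[1]]
  cut_after <- which(res %in% c("K", "R"))
  if (proline_rule)
    cut_after <- cut_after[!(cut_after < len & res[cut_after + 1L] == "P")]
  bounds <- unique(c(0L, cut_after[cut_after < len], len))
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  n_frag <- length(starts)
  out <- list()
  for (i in seq_len(n_frag)) {
    for (m in 0:missed) {
      j <- i + m
      if (j > n_frag) break
      s <- starts[i]; e <- ends[j]
      l <- e - s + 1L
      if (l < min_len || l > max_len) next
      out[[length(out) + 1L]] <- c(s, e)
    }
  }
  if (!length(out))
    return(data.frame(protein_id = character(), sequence = character(),
                      start = integer(), end = integer(),
                      aa_before = character(), aa_after = character(),
                      stringsAsFactors = FALSE))
  se <- do.call(rbind, out)
  data.frame(protein_id = protein_id,
             sequence = substring(sequence, se[, 1], se[, 2]),
             start = se[, 1], end = se[, 2],
             aa_before = ifelse(se[, 1] == 1L, "-",
                                substring(sequence, se[, 1] - 1L, se[, 1] - 1L)),
             aa_after = ifelse(se[, 2] == len, "-",
                               substring(sequence, se[, 2] + 1L, se[, 2] + 1L)),
             stringsAsFactors = FALSE)
}
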