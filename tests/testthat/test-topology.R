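make_annotation <- function(protein_id, keywords, topology, sequence_length) {
  df <- data.frame(protein_id = protein_id, sequence_length = sequence_length,
                   stringsAsFactors = FALSE)
  df$keywords <- list(keywords)
  df$topology <- list(topology)
  df
}

type1_annotation <- function(pid = "P1", len = 300L, tm_start = 151L) {
  make_annotation(pid, c("membrane", "transmembrane_single_pass"),
                  data.frame(kind = c("extracellular", "transmembrane", "intracellular"),
                             start = c(1L, tm_start, tm_start + 21L),
                             end = c(tm_start - 1L, tm_start + 20L, len)),
                  len)
}

make_peptide <- function(pid, s, e, seq = strrep("A", e - s + 1L),
                         before = "K", after = "G") {
  data.frame(protein_id = pid, sequence = seq, start = s, end = e,
             aa_before = before, aa_after = after, stringsAsFactors = FALSE)
}

test_that("peptides map to ectodomain, TM-spanning and intracellular regions", {
  ann <- type1_annotation()
  pep <- rbind(make_peptide("P1", 10, 20),     # inside extracellular 1-150
               make_peptide("P1", 160, 168),   # inside TM 151-171
               make_peptide("P1", 145, 155),   # straddles: TM takes precedence
               make_peptide("P1", 200, 220),   # intracellular
               make_peptide("P1", 290, 310))   # beyond sequence end
  expect_warning(out <- map_peptides(pep, ann), "beyond")
  expect_equal(out$mapping$region,
               c("ectodomain", "transmembrane_spanning", "transmembrane_spanning",
                 "intracellular", "unresolved"))
  s <- out$summary
  expect_equal(s$n_resolved, 4L)
  expect_equal(s$fraction_ectodomain + s$fraction_transmembrane +
                 s$fraction_intracellular, 1)
})

test_that("mapping is restricted to single-pass TM proteins and ignores segment order", {
  soluble <- make_annotation("P2", "secreted",
                             data.frame(kind = "extracellular", start = 1L, end = 100L),
                             100L)
  ann <- rbind(type1_annotation(), soluble)
  pep <- rbind(make_peptide("P1", 10, 20), make_peptide("P2", 10, 20))
  out <- map_peptides(pep, ann)
  expect_equal(out$mapping$region, c("ectodomain", "unresolved"))
  # reorder topology segments: identical calls
  ann2 <- ann
  ann2$topology[[1]] <- ann2$topology[[1]][c(3, 1, 2), ]
  out2 <- map_peptides(pep, ann2)
  expect_equal(out2$mapping$region, out$mapping$region)
})

test_that("region calls equal brute-force interval arithmetic on synthetic digests", {
  sim <- generate_secretome(sim_config(n_proteins = 40, seed = 33))
  ann <- generate_annotations_topology(sim$truth)
  pep <- generate_peptides(ann$sequences, ann$annotations, leakage = 0.05, seed = 3)
  out <- map_peptides(pep, ann$annotations)
  idx <- match(pep$protein_id, ann$annotations$protein_id)
  expected <- vapply(seq_len(nrow(pep)), function(i)
    oracle_map_region(pep$start[i], pep$end[i], ann$annotations$topology[[idx[i]]]),
    character(1))
  expect_identical(out$mapping$region, expected)
})

test_that("shed vs soluble classification follows the membrane-anchor keywords", {
  ann <- rbind(
    make_annotation("P1", "secreted",
                    data.frame(kind = character(), start = integer(), end = integer()), 100L),
    make_annotation("P2", c("gpi_anchor", "membrane", "glycoprotein"),
                    data.frame(kind = character(), start = integer(), end = integer()), 100L),
    type1_annotation("P3"),
    make_annotation("P4", "cytoplasm",
                    data.frame(kind = character(), start = integer(), end = integer()), 100L))
  out <- classify_secretion(ann)
  expect_equal(out$classes$class,
               c("soluble_secreted", "shed_membrane", "shed_membrane", "other"))
})

test_that("per-group shed/soluble percentages recover a planted composition", {
  sim <- generate_secretome(sim_config(n_proteins = 800, seed = 35))
  ann <- generate_annotations_topology(sim$truth)
  detected <- list(neuron = ann$annotations$protein_id)
  out <- classify_secretion(ann$annotations, detected, glyco_only = FALSE)
  comp <- out$composition
  # planted: shed = single TM (0.40) + GPI (0.05), soluble = 0.45
  expect_equal(comp$pct_shed / 100, 0.5, tolerance = 0.1)
  expect_equal(comp$n_shed + comp$n_soluble,
               sum(out$classes$class != "other"))
})

test_that("cleavage calls implement the trypsin rule with terminal exceptions", {
  seqs <- c(P1 = "MKTAYIAKQRQISFVKSHFSR")
  # K at 8, R at 10; peptide 9-15 "QRQISFV" no wait; construct directly:
  pep <- rbind(
    data.frame(protein_id = "P1", sequence = "TAYIAK", start = 3, end = 8,
               aa_before = "K", aa_after = "Q", stringsAsFactors = FALSE),   # tryptic
    data.frame(protein_id = "P1", sequence = "QISFVK", start = 11, end = 16,
               aa_before = "R", aa_after = "S", stringsAsFactors = FALSE),   # tryptic
    data.frame(protein_id = "P1", sequence = "ISFVK", start = 12, end = 16,
               aa_before = "Q", aa_after = "S", stringsAsFactors = FALSE),   # semi (N)
    data.frame(protein_id = "P1", sequence = "QISF", start = 11, end = 14,
               aa_before = "R", aa_after = "V", stringsAsFactors = FALSE),   # semi (C)
    data.frame(protein_id = "P1", sequence = "MKTAYIAK", start = 1, end = 8,
               aa_before = "-", aa_after = "Q", stringsAsFactors = FALSE),   # N-terminus
    data.frame(protein_id = "P1", sequence = "SHFSR", start = 17, end = 21,
               aa_before = "K", aa_after = "-", stringsAsFactors = FALSE),   # C-terminus
    data.frame(protein_id = "P1", sequence = "AYI", start = 4, end = 6,
               aa_before = "T", aa_after = "A", stringsAsFactors = FALSE))   # non-tryptic
  out <- call_cleavage(pep, seqs)
  expect_equal(out$specificity,
               c("tryptic", "tryptic", "semi_tryptic", "semi_tryptic",
                 "tryptic", "tryptic", "non_tryptic"))
  # nominated cleavage: residue before the peptide for N-side, last residue for C-side
  expect_equal(out$cleavage_position, c(NA, NA, 11L, 14L, NA, NA, NA))
  # flank inconsistent with the sequence is a hard error
  bad <- pep[1, ]; bad$aa_before <- "L"
  expect_error(call_cleavage(bad, seqs), "aa_before mismatch")
})

test_that("a perfect tryptic digest yields 100% tryptic calls", {
  set.seed(6)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:5) {
    seq <- paste(sample(aa, 400, replace = TRUE), collapse = "")
    seqs <- c(X1 = seq)
    pep <- tryptic_digest(seq, "X1")
    if (!nrow(pep)) next
    out <- call_cleavage(pep, seqs)
    expect_true(all(out$specificity == "tryptic"))
  }
})

test_that("the digest emits correct fragments and missed cleavages", {
  # cut sites after K (pos 4) and R (pos 9); length bounds disabled
  seq <- "AAAKBBBBRCCCC"
  pep <- tryptic_digest(seq, "T1", missed = 1, min_len = 1, max_len = 100)
  expect_setequal(pep$sequence,
                  c("AAAK", "BBBBR", "CCCC", "AAAKBBBBR", "BBBBRCCCC"))
  expect_equal(pep$aa_before[pep$sequence == "BBBBR"], "K")
  expect_equal(pep$aa_after[pep$sequence == "BBBBR"], "C")
})

test_that("the proline exception is off by default and switchable", {
  seq <- "AAKPBBKCC"
  default <- tryptic_digest(seq, "T1", missed = 0, min_len = 1, max_len = 100)
  expect_true("AAK" %in% default$sequence)
  strict <- tryptic_digest(seq, "T1", missed = 0, min_len = 1, max_len = 100,
                           proline_rule = TRUE)
  expect_false("AAK" %in% strict$sequence)
  expect_true("AAKPBBK" %in% strict$sequence)
})
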