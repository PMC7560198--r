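Package: secretomapper
Title: Cell-Type-Resolved Secretome Quantification and Origin Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of label-free quantification (LFQ) secretome
    proteomics across brain cell types: replicate-presence filtering,
    left-shifted Gaussian imputation of left-censored missing values,
    moderated empirical-Bayes and SAM-style s0 permutation differential
    abundance tests, a two-rule cell-type-specific secretion classifier,
    peptide-to-ectodomain topology mapping with semi-tryptic cleavage-site
    calling, quartile mapping of body-fluid proteomes to cell-type origin,
    a secreted-ligand to membrane-receptor interaction map, and a synthetic
    data generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
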