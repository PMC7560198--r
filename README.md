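# secretomapper

Downstream analysis of cell-type-resolved secretome proteomics. The package
takes label-free quantification (LFQ) protein-group tables — the kind a
MaxQuant/Spectronaut search produces for secretomes of cultured brain cell
types (astrocytes, microglia, neurons, oligodendrocytes), CSF or brain
slices — and carries them through the statistical pipeline that turns raw
intensities into biology:

1. **Preprocessing** — replicate-presence filtering (a protein must be
   quantified in ≥ 5 of 6 biological replicates of at least one cell type),
   log2 transform, and imputation of left-censored missing values from a
   left-shifted Gaussian (down-shift 1.8 column SDs, width 0.3 SDs).
2. **Differential abundance** — protein-wise linear models with
   empirical-Bayes variance shrinkage (moderated t, Bonferroni p < 0.05 and
   |log2 FC| ≥ 2), a SAM-style s0 permutation test (P = 0.05, s0 = 0.1) for
   volcano analyses, and the plain two-sample t.
3. **Cell-type-specific secretion** — the two-rule classifier: a protein is
   specifically secreted by one cell type if detected there in ≥ 5/6
   replicates and either (i) detected in ≤ 2 replicates of every other cell
   type, or (ii) ≥ 5-fold enriched against every other cell type. A
   companion 2.5-fold rule assigns lysate (expression) specificity, and the
   concordance step separates expression-driven from secretion-specific
   proteins.
4. **Topology** — mapping of peptides onto UniProt-style membrane topology
   (ectodomain / TM-spanning / intracellular), shed-vs-soluble
   classification (single-pass TM or GPI-anchored ⇒ shed ectodomain), and
   semi-tryptic peptide calling to nominate protease cleavage sites.
5. **Origin mapping** — quartile binning of a body-fluid proteome (CSF:
   ≥ 3/4 replicates) by abundance and lookup of each fluid protein's
   cell types of origin in the secretome resource; disease-association
   joining at evidence index ≥ 0.9.
6. **Interaction map** — secreted-ligand → membrane-receptor edges between
   cell types from binary interaction tables.
7. **Synthetic data** — a generator with planted ground truth (log-normal
   abundances, ≥ 5-fold planted effects, logistic left-censoring) so every
   stage is testable at desk scale.

## The statistics in brief

For protein *g* with pooled two-group residual variance *s²_g* on *d_g*
degrees of freedom, the moderated t shrinks the variance toward a prior
(*d₀*, *s₀²*) estimated by moment-matching of log *s²_g* across proteins
(digamma/trigamma inversion):

    s̃²_g = (d₀·s₀² + d_g·s²_g) / (d₀ + d_g),   t̃_g ~ t(d_g + d₀)

The SAM-style statistic adds a fudge constant to the denominator,
*t_g = Δ_g / (se_g + s0)*, and the |t| cutoff is calibrated so the
permutation-estimated FDR (mean permuted exceedance count over observed
count, π₀ = 1) stays below α.

Imputation replaces each missing value in a sample column with observed
mean *m* and SD *s* by a draw from Normal(*m* − 1.8 *s*, (0.3 *s*)²),
modeling intensities missing because they fell below the detection limit.

## Worked example

```r
library(secretomapper)

sim <- generate_secretome(sim_config(n_proteins = 1000, seed = 42))
sim$table
#> intensity_table: 1000 proteins x 24 samples [raw scale]
#>   groups: astrocyte, microglia, neuron, oligodendrocyte
#>   missing: 2436 cells; imputed: 0 cells

filtered <- filter_by_replication(sim$table, min_detected = 5)
attr(filtered, "report")
#> $kept    [1] 942
#> $removed [1] 58

imputed <- impute_left_shifted(log_transform(filtered, 2), seed = 42)
calls <- classify_specificity(detection_counts(filtered), group_means(imputed))
table(calls$rule)
#>                both exclusive_detection     fold_enrichment                none
#>                   2                   6                 274                 660

head(calls[!is.na(calls$specific_group), ], 3)
#>    protein_id specific_group            rule min_pairwise_fold
#> 9     SP00009      microglia fold_enrichment          9.915145
#> 14    SP00015         neuron fold_enrichment          5.997206
#> 16    SP00017      microglia fold_enrichment          6.417162

da <- moderated_pairwise_da(imputed, "neuron", "astrocyte")
sum(da$significant)   # Bonferroni p < 0.05 and |log2FC| >= 2
#> [1] 145
```

Of the 1000 simulated proteins, 942 survive the 5-of-6 filter; 282
receive a cell-type-specific call, almost all by the fivefold rule (the
generator plants 30% specific proteins at eightfold, but some fall below
the detection bar or the filter). Against the planted truth this run
recovers specificity with sensitivity 0.956 and precision 0.996.

An end-to-end run (`run_pipeline()`) chains these stages with topology
mapping, fluid-origin assignment and the interaction map, and writes TSV
outputs plus a JSON summary and MANIFEST when given an output directory.

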