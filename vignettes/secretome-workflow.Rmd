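---
title: "Methods: cell-type-resolved secretome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-resolved secretome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretomapper)
```

This vignette documents the statistical model behind each pipeline stage,
the parameters that matter, the numerical choices we pinned where the
field's conventions leave room, and what the synthetic-data tests do and do
not establish about real data.

## The data model

The central object is an `intensity_table`: a protein × sample matrix of
LFQ intensities with an explicit missing state (`NA`, never 0), a sample
design binding columns to cell types and replicates, and two logical masks.
`detected` freezes which cells held a genuine measurement at ingestion;
`imputed` marks cells later filled in. All detection counting — the
replicate filter, the specificity rules, the resource lookup — uses the
`detected` mask, so imputation can never manufacture a detection. This
separation is the single most important bookkeeping rule in the package:
conflating "has a value after imputation" with "was quantified" silently
inflates every downstream count.

Missing values in LFQ secretome data are overwhelmingly left-censored:
a protein drops out of a sample because its intensity fell below the
instrument's detection limit, not at random. Ingestion therefore treats a
0, an empty cell or `NaN` text in a protein-group table as missing
(MaxQuant writes 0 for non-quantified proteins), and raw-scale tables are
strictly positive by construction.

## Preprocessing

**Replicate filter.** A protein enters the resource when quantified in at
least `min_detected` (default 5) of the replicates of at least one cell
type. The filter runs after decoy/contaminant removal; whether to filter
before or after flag removal is not externally constrained, and filtering
after is the only order under which the flags can do their job.

**Imputation.** Each missing entry in a sample column with observed mean
$m$ and standard deviation $s$ is replaced by a draw from
$\mathcal{N}(m - 1.8\,s,\ (0.3\,s)^2)$. The down-shift places imputed
values below the bulk of the observed distribution — where censored
intensities actually live — while the narrow width keeps them from
dominating variance estimates. Column-wise moments (rather than a single
global pair) follow the Perseus default that this workflow style implies;
per-column moments also absorb modest sample-to-sample sensitivity
differences. Columns are filled left to right from one seeded generator,
so results are bit-reproducible; present values are never touched.
Imputation requires at least two present values per column and refuses to
run otherwise — a column that sparse signals that filtering was skipped.

## Differential abundance

**Moderated t.** For a pairwise contrast the per-protein pooled residual
variance $s_g^2$ (df $d_g = n_A + n_B - 2$) is shrunk toward a prior
$(d_0, s_0^2)$ estimated by moment-matching the distribution of
$\log s_g^2$ across proteins, inverting digamma/trigamma functions by
Newton iteration; the moderated t then has $d_g + d_0$ df. This is the
standard empirical-Bayes scheme for small-replicate omics, and the test
suite verifies our implementation against `limma` to ~1e-8 on shared
inputs — limma serves as an independent oracle there, never as the
implementation. With fewer than 10 proteins no prior can be estimated
sensibly and the test falls back to the ordinary t ($d_0 = 0$).
Significance requires both a Bonferroni-corrected $p < \alpha$ (default
0.05) and $|\log_2 \mathrm{FC}| \ge 2$; the fold-change bar exists because
imputed values can generate large but meaningless t statistics for
proteins missing in one condition, and a two-unit log2 bar suppresses
those.

**s0 permutation test.** The SAM-style statistic
$t_g = \Delta_g / (\mathrm{se}_g + s_0)$ (default $s_0 = 0.1$) damps
significance of tiny fold changes. The |t| cutoff is calibrated so that
the permutation-estimated FDR — mean count of permuted-label proteins
beyond the cutoff divided by the observed count — is at most $\alpha$.
Choices we pinned because the Perseus-compatible behavior is not fully
published: label permutations are drawn from the distinct assignments of
samples to groups, excluding the identity (and its complement for balanced
designs); `n_perm = 250` by default, enumerated exhaustively below 20
distinct permutations (with a warning); $\pi_0$ is fixed at 1, which is
conservative; the exceedance summary across permutations is the mean.
Acceptance of these defaults is validated behaviorally: under a simulated
global null the mean significant fraction stays below $\alpha$, and at
$s_0 = 0$ the statistic collapses to the classical t to 1e-12.

**Pooled vs Welch.** Both the plain and the s0 test use pooled-variance t
(the SAM lineage); replicate counts are balanced by design, where pooled
and Welch nearly coincide.

**Exclusive proteins.** A protein detected in only one of the two
conditions has no meaningful p-value after imputation; such proteins are
reported in a separate `exclusive` attribute instead.

## The specificity rules

A protein is cell-type-specifically secreted by group $g$ iff it is
detected in $\ge$ 5/6 replicates of $g$ and (i) detected in $\le 2$
replicates of *every* other group, or (ii) $\ge$ 5-fold enriched (on
imputed log2 group means) against *every* other group. Two readings of
rule (i)'s "another cell type" exist; we enforce "every other cell type",
the reading consistent with how exclusive detection is described alongside
the shed/soluble splits. Fold enrichment is computed as a difference of
imputed log2 group means, not a ratio of raw means, because the workflow
imputes before any comparison. Rule (ii) can name at most one group
(strict dominance); if two groups tie under rule (i) — possible only when
the detection bar does not exceed the exclusion bar, as in the
2-replicate lysate setting — the protein is called none and the conflict
logged.

We deliberately keep a second, weaker notion separate:
`uniquely_detected()` reports proteins reaching the detection bar in
exactly one group regardless of sub-bar detection elsewhere. Conflating
"uniquely detected" with "cell-type-specific" is the likeliest
reimplementation error in this analysis family, so both counters exist and
are tested against each other.

Lysate specificity uses the fold rule alone at 2.5-fold, with a
2-replicate inclusion bar, mirroring how expression specificity is defined
for cultured brain cells. The concordance step then classifies each
specifically secreted protein as expression-driven (same lysate-specific
group), secretion-specific (covered by the lysate data but not specific
there — the signature of cell-type-specific shedding or export), or
secretome-only (absent from the lysate dataset).

## Topology, shedding and cleavage sites

Peptide mapping is restricted to single-pass TM proteins — multi-pass
topology makes "the" ectodomain ambiguous, so those peptides are
`unresolved`. A peptide overlapping the TM segment is
`transmembrane_spanning` even if it also touches the ectodomain; this
precedence keeps the ectodomain fraction strict. Type-II orientation is
honored: ectodomain means the extracellular-annotated segments, wherever
they lie. Coordinates are 1-based inclusive throughout.

Shed-vs-soluble classification is annotation-driven: single-pass TM or
GPI-anchored ⇒ `shed_membrane` (the protein can only reach the secretome
as a proteolytically released ectodomain), secreted without membrane
anchoring ⇒ `soluble_secreted`.

The trypsin rule (cut after K/R) ignores the proline exception by default,
matching common search-engine leniency; it is switchable
(`proline_rule = TRUE`). A peptide terminus is tryptic when preceded by
K/R or coinciding with a protein terminus; exactly one non-tryptic
terminus makes the peptide semi-tryptic and nominates the endogenous
cleavage position (the residue before the peptide for N-side, the last
residue for C-side). Flanking residues are cross-checked against the
sequence and a mismatch is a hard error — silent coordinate drift is how
cleavage-site analyses go wrong.

## Fluid origin mapping

Fluid proteins are ranked by the mean of their present log10 LFQ values —
no imputation enters the ranking, since imputed values would pull
low-detection proteins toward an arbitrary bin. The four bins take sizes
$\lceil n/4 \rceil$-first (n = 10 gives 3, 3, 2, 2); ties break by
accession so the binning is deterministic. The CSF convention filters at
$\ge$ 3 of 4 replicates. Resource membership per cell type requires
$\ge$ 5/6 detection in that cell type; a fluid protein contributes to
every cell type that detects it, so per-quartile composition bars may sum
above 100% — that is the intended semantics, not double counting.

Disease associations are retained at evidence index $\ge$ `ei_min`. The
curation-score cutoff appears in two variants in this analysis family
(0.95 for the search, 0.9 for reported associations); we default to 0.9 —
the value under which results are actually reported — and expose it as a
parameter.

## The synthetic generator

`generate_secretome()` draws protein baselines from
$\mathcal{N}(25, 2^2)$ on the log2 scale, plants a specific group for 30%
of proteins with an eightfold (log2 = 3) enrichment, adds replicate noise
(SD 0.5), and censors detection through a logistic model centered at log2
intensity 22 with slope 1.5 — missingness is therefore monotone in
intensity, the MNAR structure the imputation assumes. A smooth logistic
(rather than hard truncation) gives imputation-bias tests a continuous
target; `hard_censoring = TRUE` provides the truncation variant. Defaults
mirror the study design the pipeline targets: 4 cell types × 6
replicates, CSF-style fluids at 1 × 4.

The generator emulates: log-normal abundance, planted specificity at
effect sizes above the calling threshold, left-censored missingness,
UniProt-style annotation/topology structure (45% soluble secreted, 40%
single-pass TM, 5% GPI), tryptic digestion with missed cleavages, a
configurable intracellular-peptide leak (default 0.001), and fluid
proteomes as weighted mixtures of cell-type secretomes. It does **not**
emulate: peptide detectability and protein-inference artifacts, shared
peptides between homologs, batch effects or chromatographic drift,
normalization residuals, or correlated missingness between samples.
Passing tests therefore establish that the algorithms are correct under
the stated statistical model — filter counts exact, imputation
distributionally faithful, classifiers equal to brute-force oracles, tests
calibrated under the null — not that the pipeline is robust to every
artifact of real acquisitions.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen so the full battery
completes in well under a minute while keeping binomial error bands tight
enough to be meaningful: imputation moments on 10,000 draws; specificity
recovery at the full study design (2,000 proteins × 4 × 6) over 5 seeds;
null calibration over 100 runs of 200 proteins (moderated) and 20 runs
(s0 permutation, 250 permutations each); oracle-equality sweeps on
100-protein instances over 20 seeds. Floating-point equalities are
asserted at 1e-12 where an algebraic identity is claimed (s0 = 0 limit,
Pearson formula), 1e-9 where two routes accumulate rounding differently
(moderated vs classical t), and statistical checks use fixed seeds so the
suite is deterministic.

Other numerical choices: Newton iteration for the trigamma inverse with
relative tolerance 1e-10; correlation matrices symmetrized exactly and
sample pairs sharing fewer than 3 values set to missing; quartile ties
broken lexicographically; the permutation universe enumerated whenever it
is small enough to hold, sampled without replacement otherwise.

## Known limitations

- Pairwise contrasts only; no multi-factor designs or covariates.
- Membership-style fluid mapping only — no proportional deconvolution of
  fluid abundances onto cell-type profiles.
- Topology must be supplied; the package does not predict it.
- The permutation FDR follows our documented scheme and is not guaranteed
  to match any specific desktop tool bit-for-bit.
- Annotation-driven shedding classification inherits the completeness of
  the supplied keyword table.
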