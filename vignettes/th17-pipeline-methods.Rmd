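---
title: "Methods: models, parameters and design choices of the th17translate pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices of the th17translate pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(th17translate)
```

# The problem

Severe asthma contains a corticosteroid-refractory, neutrophilic
sub-population whose airway transcriptome carries a Th17/IL-17 imprint
rather than the classical Th2 (eosinophilic) signature. Evaluating a
drug against that endotype requires three computational bridges: calling
the endotype in patient cohorts from a small surrogate gene signature,
showing that a mouse disease model deregulates the same genes as the
patients (and that treatment reverses them), and quantifying, per dose,
how strongly the pathway cytokines are suppressed in vivo. This package
implements those bridges as reusable, seeded, fully testable components.

# Signature scoring and endotype clustering

The score is deliberately primitive: per-gene mean-centering across
samples followed by averaging over the signature genes. Assumptions:

- expression is on a roughly additive (log-like) scale, so a per-gene
  shift is meaningful;
- the cohort is the reference population — centering makes every score a
  *within-cohort* contrast, so scores sum to zero by construction and a
  "high" call means "high relative to this cohort", not an absolute
  expression level;
- signature genes are co-regulated enough that their centered average
  suppresses gene-level noise (4 genes already halve the per-gene sd).

Tunables: `cutoff` (default 0 on the centered scale — the natural
midpoint of a within-cohort contrast) and `min_genes` (default 1; genes
absent from the matrix are dropped silently, mirroring the common
practice of scoring over whichever probes survived QC). A score exactly
at the cut-off is called **low**: the boundary side is not determined by
the method's definition, and a closed lower side keeps the rule
deterministic; with continuous scores the event has probability zero.

With two signatures (Th2 and Th17) the composite high/low pair yields up
to four clusters. Which of the four are occupied is a property of the
data, not the method; the package reports all occupied combinations and
leaves naming to the analyst. Prevalence percentages are reported at
full precision plus a rounded column using round-half-away-from-zero,
the convention of printed clinical tables.

# Cross-study correlation

Each study is FDR-filtered first (`p_adj_fdr <= alpha`, default
`alpha = 0.05`, boundary retained), then pairs are inner-joined on
harmonized symbols and Pearson `r` is computed on the paired log2 fold
changes. Filtering **before** joining means each study's significance
call is marginal, not joint; the joined set is the intersection of the
two filtered sets. This is one of two defensible readings of
per-dataset filtering; the package defaults to it because it treats each
study's own error control as authoritative, and the alternative (filter
on the union, or correlate all shared genes) is reachable by setting
`alpha = 1` before joining.

Selection inflates correlation: conditioning on significance enriches
for large latent effects, so the observed `r` among surviving genes
typically exceeds the unconditional population correlation (the README's
worked example shows 0.83 observed against 0.7 planted). Recovery
checks against the generator therefore run unfiltered.

The p-value uses the two-sided t approximation with `n - 2` degrees of
freedom — standard for Pearson correlation and adequate at the `n` of
genome-scale joins. Pairs with fewer than 3 shared genes are reported
as `NA` cells (never 0, which is a valid correlation), and a matrix run
continues past them.

Cross-species harmonization translates symbols through a two-column
ortholog map; unmapped genes are dropped and counted, and many-to-one
translations collapse by the arithmetic mean — the same dedup rule used
everywhere in the package because it is order-independent and
deterministic.

# Weighted sliding-window cell-type enrichment

The ranking universe is fixed at the top 2000 genes by descending signed
fold change (20 weight blocks × 100 genes). Ranking by *signed* fold
change reflects the intended use — detecting infiltrating cell types
whose markers are up-regulated; `absolute = TRUE` is available when
direction is not of interest. Ties (identical fold changes) break
lexicographically by symbol so rankings are reproducible across
platforms.

The weighted score is defined purely on the 100-gene blocks: a marker at
rank 1–100 contributes 20, at 101–200 contributes 19, down to 1 for
1901–2000 and 0 beyond. The size-200 window is exposed separately
(`windowed_overlap()`, step 100 so windows align with block boundaries)
as a positional diagnostic: the relationship between the 200-gene window
scan and the 100-gene weight blocks is genuinely ambiguous in the
method's published description, so the package keeps the two readings as
two functions rather than blending them. Under a uniformly random
ranking the expected score for `m` markers in a `G`-gene universe is
`m · 21000 / G` (each of the 2000 weighted slots carries average weight
10.5), which the test suite verifies empirically; no significance claim
is attached.

# Digital cell quantification

The fold-change vector is modelled as a linear mixture of cell-type
reference profiles; the mixing weights (signed relative abundance
changes) are estimated by elastic net with mixing parameter
`alpha = 0.05` — heavily ridge-leaning, the regime of the original
algorithm, which stabilizes correlated compendium columns while the
small L1 component still zeroes inactive cell types. The 100-step
regularization path stops at `0.2 · λ_max` (`lambda_min_ratio = 0.2`)
and coefficients are read at the final λ. Repeats (default 3) each use
a seeded random half of the shared genes (`subsample = 0.5`) and are
averaged; the repeat spread is reported as a per-cell-type sd. The
reference implementation of the algorithm instead permutes/subsamples
compendium *columns* with fraction 1.0 by default, which leaves the fit
essentially unchanged between repeats; gene subsampling makes the
repeats informative, which is why this package uses it.

**Debiasing (a deliberate design choice).** At `λ = 0.2·λ_max` with
`alpha = 0.05`, the penalty is large: on a near-orthogonal compendium
the fitted coefficients are shrunk to roughly one fifth of the true
mixing weights (the shrinkage ratio is scale-invariant, so no rescaling
of inputs removes it). Selection, however, is accurate. The default
`debias = TRUE` therefore uses the penalized fit only to select the
active cell types and reports an ordinary least-squares refit on that
support (a relaxed elastic net): noise-free mixtures are then recovered
at their true magnitudes, and the 2.0 quantity filter operates on an
interpretable scale. `debias = FALSE` reproduces the raw path
coefficients of the reference implementation.

Post-processing follows the published workflow: quantities are averaged
per sample group and cell types are removed when their group means never
reach 2.0. Because quantities are signed, the default filter compares
`|group mean|` to the threshold — a literal one-sided reading would
delete every *depleted* cell type, which contradicts the workflow's own
display of down-regulated rows; `signed = TRUE` restores the literal
reading. The boundary is inclusive: a mean of exactly 2.0 survives
("below 2.0" removes only strictly smaller values). The z-score
transform standardizes each cell type across groups; zero-variance rows
are dropped with a warning since they carry no contrast.

# Pharmacodynamics

Percent inhibition anchors a treated group's mean between the
vehicle-treated negative control (100%) and positive control (0%):
`%inh = 100 − (Y/K1)·100`, `K1 = mean(pos) − mean(neg)`,
`Y = mean(treated) − mean(neg)`. The quantity is affine-invariant in
the endpoint's units, may legitimately exceed 100% (treated below the
negative control) or go negative (worse than the positive control), and
is never clipped in computation; only the tabular efficacy report floors
negatives at 0 for display, keeping the raw matrix attached.
`K1 = 0` (controls coincide) leaves the normalization undefined and is
an error, not a silent NA.

The exposure–response layer fits `I(c) = I_max·c^h/(EC50^h + c^h)` by
least squares on `(log EC50, log h)` — positivity is structural and the
optimizer (`nlminb`, relative tolerance 1e-15) sees an unconstrained
smooth problem. Starting values are deterministic and scale-aware:
`EC50` at the geometric mean of the exposures, `h = 1`. `I_max` is
fixed at 100% by default because inhibition is already a normalized,
bounded quantity; whether the original curves fixed or fitted the
ceiling is not documented, so `fix_imax = FALSE` (requiring a fourth
distinct exposure) is provided. The fitted curve is monotone
non-decreasing for `h > 0`, and `inhibition_at()`/`exposure_at()` are
closed-form mutual inverses on `0 < I < I_max`.

# What the synthetic generators emulate — and what they do not

Every generator is a pure function of its arguments including the seed
(RNG state is saved and restored, so generators never perturb the
caller's stream). Defaults state the modelled world once:

- `gen_deg_studies`: one latent per-gene effect plus independent study
  noise scaled to a target pairwise correlation
  (`noise_sd = latent_sd·sqrt((1−ρ)/ρ)`, default ρ = 0.7, 2000 genes);
  p-values from a z-model, BH-adjusted.
- `gen_cohort_matrix`: Normal(0, 1) baseline, 60 samples, 40% planted
  signature-high at +2 sd on the 4 signature genes — a separation at
  which the score rule recovers labels at roughly 95%, i.e. the regime
  of a clear but not trivial endotype.
- `gen_mixture_foldchange`: 500 genes, 10 cell types, 30 distinctive
  markers per type (+5 over a Normal(0, 1) background), 2-sparse truth
  (+5/−3). Compendium columns are scaled to unit variance: deconvolution
  weights are only defined relative to a declared compendium scale, and
  unit-variance reference profiles make the generator's `w_true`, the
  standardized-scale fit and the 2.0 filter threshold commensurable.
- `gen_ranked_planting`: markers placed at exact ranks with strictly
  decreasing fold changes, so enrichment scores have a closed-form
  truth.
- `gen_pd_table`: saline n = 6, challenged vehicle n = 8, dosed arms
  n = 8 (the group sizes of the modelled in-vivo design); doses
  1/3/10/30 with linear dose→trough mapping (40 nM per unit dose);
  IL-17 EC50 120 nM, IL-22 600 nM (a 1:5 potency shift), Hill slope
  1.5; neutrophils track IL-17; eosinophils are an untouched Th2
  endpoint (`I_max = 0`). Noise is Normal per animal, sd expressed as a
  fraction of each endpoint's induction (`cv`, default 0).

Not emulated: probe-level artefacts, batch and library-size effects,
count-distribution (negative-binomial) noise, correlated gene modules
beyond the single latent factor, compendium column correlation
structure of real immune lineages, animal-level correlation across
endpoints, and non-linear PK. A green recovery test therefore
establishes that the algorithms are implemented correctly and are
statistically consistent in their stated regime — not that they are
robust to everything real data does.

# Numerical conventions

- Duplicate symbols anywhere collapse by the arithmetic mean of numeric
  columns, with a warning carrying the merged count; readers never drop
  rows silently.
- Symbols are uppercased and trimmed before any matching (mixed-case
  mouse vs upper-case human nomenclature).
- Delimiters are auto-detected between tab and comma from the header
  line; tab wins ties and an explicit `sep` overrides.
- All boundary rules are inclusive-by-documentation: `p_adj <= alpha`
  retained, score `== cutoff` is low, group mean `== 2.0` retained,
  rank 2000 weighs 1 and rank 2001 weighs 0.
- The pipeline writes plain TSV with headers; re-running a config
  reproduces every output byte-identically (the manifest and config echo
  contain the run path and wall-clock and are excluded from that claim).

# Known limitations

- The endotype rule is a thresholded score, not a clustering algorithm;
  it cannot discover structure outside the provided signatures, and the
  Th2 surrogate panel is an input with no default.
- Enrichment scores carry no permutation p-value by default; the closed
  form above describes the null mean only.
- DCQ assumes the compendium spans the active cell types; a missing
  lineage is absorbed into correlated columns, and quantities are
  relative changes on the standardized compendium scale, not cell
  counts or fractions.
- The Hill layer fits group-mean inhibition, not animal-level data, so
  it propagates no within-group uncertainty into EC50.
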