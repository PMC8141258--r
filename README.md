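# th17translate

Translational transcriptomics of the Th17/IL-17 axis, from severe-asthma
patient cohorts down to mouse pharmacology. The package is for
computational biologists and DMPK/pharmacology modellers who need the
bridge computations between a clinical transcriptome, a mouse disease
model, and a dose–response readout, with every stage testable offline on
synthetic data of known structure.

## What it computes

- **Signature-score endotyping.** For a gene-by-sample expression matrix
  `X`, each gene is mean-centered across samples and the per-sample score
  for a signature `S` is `score(j) = (1/|S|) Σ_{g∈S} (x_gj − x̄_g)`.
  Samples with `score > 0` form the signature-high cluster (e.g. the
  Th17-high endotype from the CXCL1/CXCL2/CXCL3/IL-8 surrogate panel);
  prevalence is reported as counts and percentages.
- **Cross-study DEG correlation.** Each study's differential-expression
  table is filtered at `p.adj.fdr ≤ 0.05` (Benjamini–Hochberg), mouse
  symbols are harmonized to human orthologs, and the Pearson `r` of the
  log2 fold changes is computed on the inner join of each study pair,
  with `n` and a two-sided t-test p-value per cell.
- **Weighted sliding-window cell-type enrichment.** Genes ranked
  descending by fold change and truncated to 2000; a marker at rank
  1–100 contributes weight 20, 101–200 weight 19, ... 1901–2000 weight 1,
  so `score = Σ_b (21−b)·|markers ∩ block_b|` per cell-type list, with a
  size-200/step-100 window scan as a positional diagnostic.
- **Digital cell quantification (DCQ).** Elastic-net regression
  (`α = 0.05`, 100-step path stopped at `0.2·λ_max`) of a fold-change
  vector on a column-standardized immune-cell compendium, averaged over
  3 seeded gene-subsample repeats; by default coefficients are debiased
  by an OLS refit on the selected support (see the methods vignette).
  Post-processing: per-group means, removal of cell types whose
  |group mean| never reaches 2.0, and per-cell-type z-scores.
- **Pharmacodynamics.** Percent inhibition
  `100 − (Y/K1)·100` anchored on vehicle-treated negative/positive
  control group means, and a Hill exposure–response fit
  `I(c) = I_max·c^h/(EC50^h + c^h)` (default `I_max = 100`) with exact
  inverse `exposure_at()`.
- **Synthetic data + pipeline.** Seeded generators for every input above
  with returned ground truth, and `run_pipeline()` chaining
  simulate → score → xcorr → cellenrich → dcq → pd with a JSON manifest;
  identical config and seed reproduce byte-identical outputs.

## Worked example

```r
library(th17translate)

# 60-biopsy synthetic cohort, 40% planted Th17-high, shift = 2 sd
cohort  <- gen_cohort_matrix(seed = 1, n_samples = 60,
                             planted_fraction = 0.4, shift = 2)
scores   <- signature_score(cohort$matrix, default_th17_signature)
clusters <- assign_clusters(scores, cutoff = 0)
cluster_prevalence(clusters)
#>   label count percent percent_rounded
#> 1  high    27      45              45
#> 2   low    33      55              55
mean(clusters$label == cohort$truth[clusters$sample])
#> [1] 0.95

# two studies sharing a latent effect (population r = 0.7), FDR-filtered
studies <- gen_deg_studies(seed = 1, n_studies = 2, n_genes = 2000,
                           rho = 0.7)
correlate_pair(filter_degs(studies[[1]]), filter_degs(studies[[2]]))
#>   study_a study_b   n         r             p
#> 1  study1  study2 969 0.8275292 1.133694e-244

# deconvolution of a noise-free 2-sparse mixture (truth: +5 / -3)
mix <- gen_mixture_foldchange(seed = 7)
head(as.data.frame(dcq(mix$input, repeats = 3, seed = 11)), 3)
#>    cell_type quantity           sd
#> 1 celltype01        5 1.404333e-15
#> 2 celltype02       -3 3.140185e-16
#> 3 celltype03        0 0.000000e+00

# zero-noise PD table: percent inhibition equals the Hill truth
pd   <- gen_pd_table(seed = 1, cv = 0)
prof <- efficacy_profile(pd$table)
round(unclass(prof), 1)
#>             treated:1 treated:3 treated:10 treated:30
#> IL-17            16.1      50.0       85.9       96.9
#> IL-22             1.7       8.2       35.2       73.9
#> neutrophils      12.1      41.7       81.3       95.8
#> eosinophils       0.0       0.0        0.0        0.0
fit <- fit_hill(c(40, 120, 400, 1200), attr(prof, "raw")["IL-17", ])
sprintf("IL-17 EC50 = %.1f nM, h = %.2f", fit$EC50, fit$h)
#> [1] "IL-17 EC50 = 120.0 nM, h = 1.50"
```

Reading the output: 24 of 60 samples were planted high, the cut-off rule
recovers 95% of the labels (27 called high, a few low-noise samples cross
zero); FDR filtering enriches for large effects, so the observed `r` on
the 969 surviving shared genes (0.83) exceeds the population value of
0.7 planted over all genes; the noise-free mixture and the zero-noise PD
design are recovered exactly — the dosed arm at 120 nM trough sits at
exactly 50% IL-17 inhibition because 120 nM is the generator's EC50, and
the IL-22 column lags it (a 1:5 potency shift) while the Th2 endpoint
(eosinophils) is untouched.

## Documentation

Function reference via roxygen comments in `R/`; model assumptions,
parameter choices and known limitations in
`vignettes/th17-pipeline-methods.Rmd`.
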