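# chromatome

Quantitative downstream analysis of chromatin-enrichment proteomics
("chromatome") experiments in R.

Chromatin-enrichment protocols purify the chromatin-bound fraction of the
proteome; mass spectrometry then yields a wide protein-group intensity
matrix (rows = protein groups, columns = samples) per fraction, condition
and replicate. This package implements everything that happens *after*
that matrix exists, for analysts comparing chromatomes across subcellular
fractions, biological conditions (e.g. naive/formative/primed pluripotency
phases) or ChIP-MS pulldowns:

* **Import/QC** — `proteinGroups`-style TSV import with zero-to-missing
  conversion, valid-value filtering (`<2 of 3` rule), linear-scale CV
  reports.
* **Imputation** — Gaussian-downshift imputation of left-censored missing
  values: missing cells in column *j* are drawn from
  N(μⱼ − 1.8 σⱼ, (0.2 σⱼ)²) over the observed values of that column.
* **Differential testing** — SAM-style moderated statistic
  d = (x̄_A − x̄_B)/(se + s₀) with s₀ = 1, permutation-based FDR
  (default 0.05) plus a fold-change floor; one-way permutation-FDR ANOVA
  with a minimal 1.5-fold change; paired proteome-normalized chromatome
  tests; Benjamini–Hochberg adjustment.
* **Fraction classification** — z-scored six-fraction profiles, seeded
  k-means++ clustering (default k = 9) with automatic labelling of
  chromatome-enriched clusters; per-cell-line high-confidence chromatome
  (Student t, p < 0.05, FC ≥ 1.5, enrichment-directional).
* **Relative chromatin binding** — RCB = chromatome log2 − mean proteome
  log2 per condition; condition-dependent RCB detection by ANOVA
  (FDR < 0.05, FC ≥ 2) and clustering (k = 5); fold-change ranking,
  row-normalized heatmap values, Pearson correlations of layer pairs.
* **Annotation enrichment** — exact hypergeometric (Fisher) tests against
  the identified background with BH correction; strict 3-of-3 GO-category
  counts; GMT input.
* **ChIP-MS** — pulldown-vs-IgG differential enrichment (filter
  "identified < 2 of 3", FDR 5%, log2 FC cutoff 1) and bait-normalized
  iBAQ complex stoichiometry.
* **Synthetic data** — seeded simulators for fractionation, phase and
  ChIP-MS experiments with log-normal abundance, class-specific fraction
  enrichment, chromatome-only "affinity" effects and logistic MNAR
  missingness, emitting full ground truth for recovery testing.

## Worked example

Simulate a six-fraction chromatin-purification experiment, impute, run the
differential fraction analysis and extract the profile-based
high-confidence chromatome:

```r
library(chromatome)

sim <- simulate_fraction_experiment(sim_params(n_proteins = 1000, seed = 42))
sim$matrix
#> <intensity_matrix> 1000 proteins x 18 samples [log2 scale], 10.9% missing

imp <- impute_gaussian_downshift(sim$matrix, seed = 1)
res <- classify_fractions(imp, sim$design, config = test_config(seed = 2),
                          seed = 3)
res$anova
#> <differential_result> anova over 6 groups: 1000 proteins, 789 significant
res$clusters
#> <cluster_assignment> 789 proteins in 9 clusters (sizes: 3, 187, 5, 172, 27, 61, 59, 78, 197)
#>   labels: 1=mixed, 2=chromatome-enriched, 3=mixed, 4=nucleoplasmic, ...
length(res$high_confidence)
#> [1] 187

truth <- sim$truth
mean(truth$protein_id[truth$class == "chromatin_binder"] %in%
       res$high_confidence)
#> [1] 0.94
```

789 of 1000 proteins differ significantly between fractions (ANOVA
FDR < 0.05, max pairwise fold change ≥ 1.5); the cluster whose centroid
peaks only in the chromatin washes holds 187 proteins — the high-confidence
chromatome — and captures 94% of the simulated true chromatin binders
(the remainder are mostly censored low-abundance proteins).

A command-line interface mirrors the main operations
(`inst/exec/chromatome`): subcommands `simulate`, `qc`, `impute`, `diff`,
`anova`, `classify`, `relbind`, `enrich`, `chipms`, `correlate`, each with
`--design`, `--config`, `--seed`, `--out`.

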