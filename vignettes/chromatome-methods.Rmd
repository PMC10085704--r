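---
title: "Statistical methods for chromatome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for chromatome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromatome)
```

## Scope

`chromatome` implements the downstream quantitative analysis of
chromatin-enrichment proteomics experiments: wide protein-group intensity
matrices in, statistics out. The pipeline starts after raw-data processing
(DIA-NN / Spectronaut / MaxQuant); spectra, FASTA handling and figure
rendering are out of scope. All statistics operate on the log2 scale; the
`intensity_matrix` container carries an explicit scale tag that is enforced
at operation boundaries, and raw zeros are converted to missing on import
because a zero intensity means "not quantified", not "absent with intensity
one".

## Missing values and Gaussian-downshift imputation

Label-free proteomics data are left-censored: the probability that a
protein is missing rises as its abundance approaches the detection limit
(missing not at random, MNAR). `impute_gaussian_downshift()` therefore
replaces each missing cell of sample column $j$ with a draw from

$$\mathcal N\!\left(\mu_j - d\,\sigma_j,\ (w\,\sigma_j)^2\right),$$

where $\mu_j$ and $\sigma_j$ are the mean and SD of the *observed* values
of that column, the downshift defaults to $d = 1.8$ and the width to
$w = 0.2$. Imputation is column-wise (per sample), the default scope of the
Perseus implementation this mirrors. Observed cells are never altered, and
draws are seeded. The defaults are the field-standard values; changing them
changes every downstream test, so they are exposed but not encouraged.

Valid-value filtering precedes everything: `filter_min_valid()` drops
proteins with fewer than 2 of 3 quantified values in a replicate group
(scope `any_group` by default — one passing group suffices, the convention
for two-group tests), and annotation *counting* uses the stricter all-of-3
rule (`annotation_counts()`). Coefficients of variation are computed on
back-transformed linear intensities because CV% is conventionally a
linear-scale statistic; the source protocol does not state the scale, so
this choice is flagged here.

## Moderated tests with permutation-based FDR

`sam_ttest()` computes, per protein,

$$d = \frac{\bar x_A - \bar x_B}{s + s_0},$$

with $s$ the pooled-variance two-sample standard error and $s_0 = 1$ by
default. The constant $s_0$ (the SAM convention, which Perseus implements)
prevents proteins with accidentally tiny variance from dominating the top
of the ranking.

The q value is a permutation estimate: group labels are reassigned — all
distinct assignments when there are at most `n_permutations` (e.g. the 3 vs
3 design has 20), otherwise `n_permutations` random ones — and for each
candidate cutoff $c$ on $|d|$ (two-sided) or signed $d$ (one-sided),

$$\widehat{\mathrm{FDR}}(c) =
\frac{\text{mean permuted}\ \#\{|d| \ge c\}}{\#\{|d_{\mathrm{obs}}| \ge c\}}
\ \wedge\ 1 .$$

A protein's q is the smallest estimate over the cutoffs it attains, which
makes q automatically non-increasing in $|d|$. One deliberate refinement:
the *observed* label assignment — and, for two-sided statistics, its
mirror image — is excluded from the null. Both reproduce the observed
statistics exactly, so keeping them would floor every FDR estimate at
$2/n_{\text{assignments}} = 0.1$ in a triplicate design and make calls at
FDR 0.05 structurally impossible. The same rule is applied to ANOVA
permutations (shuffles that merely rename whole groups are redrawn). The
exhaustive brute-force oracle in the test suite implements the identical
estimator independently and agrees to machine precision.

Significance always couples the FDR to an effect-size floor: two-sample
calls need $|\Delta| \ge 1$ log2 unit (fold change $\ge 2$) by default;
`multi_sample_anova()` requires the largest pairwise difference of group
means to reach `log2(1.5)` (the protocol's Methods state a minimal
1.5-fold change; its Figure-2 legend says 2-fold — we follow the Methods
and leave the threshold overridable).

`paired_normalized_ttest()` tests "normalized chromatomes": replicate $i$
of the chromatome layer pairs with replicate $i$ of the proteome layer,
their difference matrix is built, and `sam_ttest()` runs between conditions
on the differences. A hit is thus a chromatome change not explained by
expression.

## Fraction-profile classification

`classify_fractions()` reproduces the differential fraction analysis: ANOVA
across the six gradient fractions (whole-cell lysate, cytoplasm, nuclei,
chromatin washes 1–3), z-scoring of the per-fraction mean profiles of
significant proteins, and k-means clustering with k-means++ initialization
and 100 restarts, keeping the lowest within-cluster sum of squares.
"Hierarchical k-means" is interpreted as k-means partitioning with
average-linkage hierarchical *ordering* of the centroids for stable,
presentation-ready cluster numbering (the heatmap behaviour of the tooling
this emulates); pure agglomerative clustering is available via
`method = "hclust"`. The default k = 9 matches the cluster count reported
for the reference six-fraction analysis, and k = 5 is the default for
relative-binding clustering.

A cluster is auto-labelled **chromatome-enriched** iff its centroid's
maxima lie only in the three chromatin-wash coordinates while the nuclei
and cytoplasm coordinates sit below the centroid mean. This rule is an
explicit, stated approximation: the original clusters were designated by
inspection, and no formal rule was published. The union of
chromatome-enriched clusters is the profile-based high-confidence
chromatome.

`define_high_confidence()` implements the per-cell-line variant: a plain
two-sample Student t test of chromatome versus proteome with raw
p < 0.05 and a one-directional fold-change floor of 1.5 (enrichment only).
Raw p — not permutation FDR — is used deliberately, because that is how
this particular threshold is stated, in contrast to the FDR-based tests
elsewhere.

## Relative chromatin binding

Relative chromatin binding (RCB) normalizes the chromatome to expression:

$$\mathrm{RCB}(p, c, r) = x^{\mathrm{chromatome}}_{p,c,r}
- \overline{x^{\mathrm{proteome}}_{p,c,\cdot}},$$

i.e. each chromatome replicate minus the mean proteome log2 intensity of
that condition. Positive RCB means more chromatin binding than expression
explains. The source description states the two subtraction orders
inconsistently; we fix the sign so that proteins *gaining* chromatin
association get *increasing* RCB, the interpretation used throughout the
results the statistic supports. RCB is kept per replicate (not per
condition mean) so that the downstream ANOVA retains within-group variance;
only the proteome side is averaged, as stated. Proteins absent from the
proteome layer get `NA` by default, or a configurable fixed value
(typically 0) with a flag — the documented fallback for bait-like proteins
never quantified in the proteome.

`rcb_anova_cluster()` then restricts to high-confidence binders, demands
ANOVA FDR < 0.05 with a 2-fold RCB change, and clusters the z-scored
condition means (k = 5).

## Enrichment and ChIP-MS

`fisher_enrichment()` computes exact hypergeometric p values (sum of table
probabilities not exceeding the observed one for the two-sided default;
upper tail for one-sided over-representation) for each annotation term
against the background of all identified proteins, with BH adjustment
across tested terms. Protein groups map to annotation identifiers by their
first id, case-insensitively. Minimal term size (default 3) is an artifact
choice exposed in configuration.

`chipms_differential()` first removes proteins identified fewer than twice
in a triplicate set, imputes, and tests pulldown versus IgG with the
moderated permutation-FDR machinery (FDR 5%); the "enriched" call
additionally requires a log2 fold change of at least 1. "Identified" means
a non-missing quantification — the protocol does not distinguish
identification from quantification at this step. Proteins never seen in
the IgG control pass through imputation like all others but carry a
`control_absent` flag. `stoichiometry()` normalizes log2 iBAQ values to the
bait per replicate and averages ratios on the log2 scale (a geometric mean
in linear space — the aggregation is unstated in the protocol, and the
geometric mean is the natural choice for ratios); the bait is exactly 1 by
construction.

## The synthetic-data generator

Real depositions are too large for desk-scale testing, so every stage is
validated against `simulate_fraction_experiment()`,
`simulate_phase_experiment()` and `simulate_chipms()`, which emit full
ground truth (never read by any analysis function). The stated world:

* **Abundance** is log-normal — Gaussian in log2 with mean 25 and SD 2,
  the typical spread of log2 LFQ intensities.
* **Latent classes** (chromatin binder 20%, nucleoplasmic 20%, cytoplasmic
  40%, background 20%) get class-by-fraction mean enrichments of ±2 log2
  units (see `default_fraction_effects()`), chosen to mirror the reported
  proportions: roughly a fifth of fraction-significant proteins fell into
  chromatome-enriched clusters, with cytoplasmic material dominating the
  rest.
* **Replicate noise** is Gaussian with SD 0.3 log2 units, consistent with
  median CVs in the few-percent range.
* **Missingness** is MNAR: a cell is missing with probability
  $\mathrm{logit}^{-1}(-s\,(x - m))$ of its *true* log2 intensity $x$,
  midpoint $m = 21$, steepness $s = 1$ — about two SDs below the abundance
  mean, yielding ~10% overall missingness concentrated in low-abundance
  proteins, which is what justifies downshift imputation. Steepness 0 is
  the documented off switch.
* **Condition effects** are drawn for a declared 10% of proteins and
  applied to both layers; **affinity effects** (chromatome-only, proteome
  truth constant) are drawn for a disjoint subset, so the true affinity
  effect equals chromatome truth minus proteome truth by construction.
  Fixed-magnitude variants (`condition_effect_size`,
  `affinity_effect_size`) exist for calibrated power checks.

No published noise model exists for these data; all effect sizes above are
artifact choices, stated once here and in the configuration surface, and
not tuned against test outcomes. The generator does not emulate peptide
level structure, shared peptides, batch effects, interference or
normalization artifacts — a green recovery test therefore establishes that
the statistics behave as specified under the stated model, not that they
are robust to everything real data does.

## Numerical and degenerate-input choices

* Constant rows z-score to all zeros (with a warning) instead of NaN.
* A protein with zero between-group sum of squares gets F = 0, not 0/0.
* Two-sample statistics with zero pooled SE fall back to a signed-infinite
  classical t (p = 0) while the moderated d stays finite through $s_0$.
* Permutation cutoffs are taken at the observed statistic values; tied
  statistics share the q of their common cutoff.
* Random permutation sampling, imputation draws and k-means restarts are
  all seeded through one documented RNG (Mersenne-Twister with inversion
  sampling), restored after use so library calls never perturb the
  caller's random stream.

## Known limitations

The identity-permutation exclusion makes small-design FDR estimates
slightly liberal relative to including it (which would make them useless);
with 18 informative assignments in a 3 vs 3 design, attainable q values
are quantized in steps of 1/18th of an exceedance ratio. The cluster
labelling rule is a heuristic stand-in for expert inspection. Fisher
enrichment does no GO-graph propagation. The CLI covers the documented
subcommands but is a thin veneer over the R API, which is the primary
interface.
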