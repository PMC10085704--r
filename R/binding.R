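# Relative chromatin binding (proteome-normalized chromatome), fold-change
# ranking, row normalization and Pearson correlations.

#' Relative chromatin binding (RCB)
#'
#' For every protein, condition and chromatome replicate computes
#' `RCB = chromatome log2 intensity - mean proteome log2 intensity across
#' that condition's replicates`. Positive values mean enrichment at
#' chromatin beyond what expression alone explains; proteome-independent RCB
#' changes indicate altered chromatin affinity or availability. RCB is kept
#' per replicate so downstream ANOVA retains within-group variance.
#'
#' Proteins missing from the proteome layer get `NA` RCB unless
#' `proteome_absent_value` is set (e.g. 0), in which case the fixed value is
#' substituted and the protein flagged.
#'
#' @param chromatome,proteome Log2 [intensity_matrix()] objects.
#' @param design A [sample_design()] covering both layers.
#' @param proteome_absent_value Optional fixed RCB for proteins without any
#'   proteome quantification in a condition (default `NULL` = `NA`).
#' @return An `rcb_profile`: `matrix` (an [intensity_matrix()] of RCB values
#'   with chromatome-replicate columns), `design` (its design),
#'   `proteome_missing` (protein x condition logical matrix of fallback use).
#' @export
relative_chromatin_binding <- function(chromatome, proteome, design,
                                       proteome_absent_value = NULL) {
  assert_log2(chromatome, "relative_chromatin_binding")
  assert_log2(proteome, "relative_chromatin_binding")
  shared <- intersect(protein_ids(chromatome), protein_ids(proteome))
  if (!length(shared)) stop_("no shared proteins between layers")
  dc <- align_design(chromatome, design)
  dp <- align_design(proteome, design)
  conds <- unique(dc$condition)
  rcb <- NULL
  flags <- matrix(FALSE, length(shared), length(conds),
                  dimnames = list(shared, conds))
  for (cc in conds) {
    cs <- dc$sample_id[dc$condition == cc]
    ps <- dp$sample_id[dp$condition == cc]
    if (!length(ps)) stop_("condition '%s' absent from the proteome layer", cc)
    pm <- rowMeans(proteome$values[shared, ps, drop = FALSE], na.rm = TRUE)
    pm[is.nan(pm)] <- NA_real_
    absent <- is.na(pm)
    block <- chromatome$values[shared, cs, drop = FALSE] - pm
    if (!is.null(proteome_absent_value)) {
      block[absent, ] <- proteome_absent_value
      flags[, cc] <- absent
    } else {
      flags[, cc] <- absent
    }
    rcb <- cbind(rcb, block)
  }
  dd <- dc[match(colnames(rcb), dc$sample_id), , drop = FALSE]
  structure(list(
    matrix = intensity_matrix(rcb, scale = "log2"),
    design = sample_design(dd$sample_id, "chromatome", dd$condition,
                           dd$replicate),
    proteome_missing = flags,
    proteome_absent_value = proteome_absent_value
  ), class = "rcb_profile")
}

#' @export
print.rcb_profile <- function(x, ...) {
  cat(sprintf("<rcb_profile> %d proteins x %d chromatome replicates over %d condition(s)\n",
              nrow(x$matrix$values), ncol(x$matrix$values),
              length(unique(x$design$condition))))
  invisible(x)
}

#' ANOVA and clustering of relative chromatin binding across conditions
#'
#' Restricts RCB profiles to high-confidence chromatin binders, tests for
#' condition-dependent RCB by [multi_sample_anova()] (default FDR 0.05,
#' minimal 2-fold change), z-scores the per-condition mean RCB of
#' significant proteins and clusters them (default k = 5).
#'
#' @param profiles An `rcb_profile` from [relative_chromatin_binding()].
#' @param high_confidence A `high_confidence_set`, or a character vector of
#'   protein ids.
#' @param config A [test_config()] for the ANOVA.
#' @param min_fc Minimal linear RCB fold change (default 2).
#' @param k Cluster count (default 5).
#' @param seed Clustering seed.
#' @param n_restarts k-means restarts.
#' @return List with `anova`, `clusters`, `z` as in [classify_fractions()].
#' @export
rcb_anova_cluster <- function(profiles, high_confidence,
                              config = test_config(), min_fc = 2, k = 5,
                              seed = 1, n_restarts = 100) {
  hc <- if (inherits(high_confidence, "high_confidence_set"))
    high_confidence$proteins else as.character(high_confidence)
  mat <- profiles$matrix
  keep <- intersect(protein_ids(mat), hc)
  if (!length(keep))
    stop_("no overlap between RCB profiles and the high-confidence set")
  mat <- mat[keep, ]
  design <- profiles$design
  conds <- unique(design$condition)
  if (length(conds) < 3) stop_("rcb_anova_cluster needs >= 3 conditions")
  # drop proteins without complete groups (NA RCB from missing layers)
  vc <- valid_counts(mat, design)
  mat <- mat[apply(vc >= 2, 1, all), ]
  res <- multi_sample_anova(mat, design, groups = as.list(conds),
                            config = config, min_fc = min_fc)
  sig_ids <- res$protein_id[res$significant]
  if (!length(sig_ids))
    return(list(anova = res, clusters = NULL, z = NULL))
  gm <- group_means(mat[sig_ids, ], design, by = "condition")
  z <- zscore_rows(gm)
  cl <- cluster_profiles(z, k = min(k, nrow(z)), seed = seed,
                         n_restarts = n_restarts)
  list(anova = res, clusters = cl, z = z)
}

#' Rank proteins by log2 fold change
#'
#' @param diff A `differential_result` (or data frame) with `protein_id` and
#'   `difference` columns.
#' @return A `rank_table` data frame sorted by descending log2 fold change;
#'   rank 1 = most enriched, ties get average ranks.
#' @export
rank_by_fold_change <- function(diff) {
  df <- as.data.frame(diff)
  if (!all(c("protein_id", "difference") %in% names(df)))
    stop_("need `protein_id` and `difference` columns")
  out <- data.frame(
    protein_id = df$protein_id,
    difference = df$difference,
    rank = rank(-df$difference, ties.method = "average", na.last = "keep"),
    significant = if ("significant" %in% names(df)) df$significant else NA,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rank_table", "data.frame")
  out
}

#' Row-normalize a matrix
#'
#' Subtracts each row's mean, the presentation used for fold-change heatmaps
#' (every output row sums to zero).
#'
#' @param m Numeric matrix with >= 2 columns.
#' @param mode Only `"subtract_row_mean"` is defined.
#' @return The centered matrix.
#' @export
row_normalize <- function(m, mode = c("subtract_row_mean")) {
  match.arg(mode)
  if (ncol(m) < 2) stop_("row_normalize needs >= 2 columns")
  m - rowMeans(m, na.rm = TRUE)
}

#' Pearson correlation of two per-protein value vectors
#'
#' Correlates two layers (e.g. chromatome vs proteome log2 fold changes, or
#' proteome vs transcriptome) over their shared, pairwise-complete proteins,
#' optionally restricted to a protein panel.
#'
#' @param layer_a,layer_b Named numeric vectors (names = protein ids).
#' @param subset Optional character vector restricting the comparison (e.g.
#'   a curated pluripotency-factor panel).
#' @return List with `r` (Pearson correlation), `n` (pairs used) and
#'   `proteins` (the ids used).
#' @export
pearson_correlate <- function(layer_a, layer_b, subset = NULL) {
  if (is.null(names(layer_a)) || is.null(names(layer_b)))
    stop_("both layers must be named by protein id")
  shared <- intersect(names(layer_a), names(layer_b))
  if (!is.null(subset)) shared <- intersect(shared, subset)
  a <- layer_a[shared]; b <- layer_b[shared]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3)
    stop_("fewer than 3 shared complete pairs (%d)", sum(ok))
  list(r = stats::cor(a[ok], b[ok], method = "pearson"),
       n = sum(ok), proteins = shared[ok])
}
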