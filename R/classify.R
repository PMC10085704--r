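# Fraction-profile classification: z-scoring, seeded k-means with
# k-means++ restarts, chromatome-enriched cluster labelling, and the
# per-cell-line high-confidence chromatome test.

#' Z-score matrix rows
#'
#' Scales every row to mean 0 and SD 1. Constant rows (SD 0) are mapped to
#' all zeros with a warning rather than producing non-finite values.
#'
#' @param m Numeric matrix with >= 2 columns.
#' @return The row-standardized matrix.
#' @export
zscore_rows <- function(m) {
  if (ncol(m) < 2) stop_("zscore_rows needs >= 2 columns")
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  flat <- !is.na(s) & s == 0
  if (any(flat))
    warn_("%d constant row(s) mapped to all-zero z-scores", sum(flat))
  s[flat] <- 1
  out <- (m - mu) / s
  out[flat, ] <- 0
  out
}

# k-means++ seeding (Arthur & Vassilvitskii): iteratively pick centers with
# probability proportional to squared distance from the nearest chosen one
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - x[rep(centers[1], n), , drop = FALSE])^2)
  for (i in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i + 1] <- sample.int(n, 1, prob = probs)
    nd <- rowSums((x - x[rep(centers[i + 1], n), , drop = FALSE])^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' Cluster z-scored profiles by restarted k-means
#'
#' Runs k-means (Euclidean distance) with k-means++ initialization and
#' `n_restarts` restarts, keeping the solution with the lowest total
#' within-cluster sum of squares. Clusters are renumbered by average-linkage
#' hierarchical ordering of their centroids so cluster indices are stable
#' and presentation-ready ("hierarchical k-means").
#'
#' @param z Numeric matrix (proteins x features), typically z-scored
#'   group-mean profiles.
#' @param k Number of clusters (1 <= k <= rows).
#' @param seed Integer seed, or `NULL`.
#' @param n_restarts Number of k-means++ restarts (default 100).
#' @param method `"kmeans"` (default) or `"hclust"` for plain agglomerative
#'   clustering (average linkage, tree cut at `k`).
#' @return A `cluster_assignment`: `cluster` (named integer vector),
#'   `centroids` (k x features), `sizes`, `tot_withinss`, `labels` (filled by
#'   [classify_fractions()]).
#' @export
cluster_profiles <- function(z, k, seed = NULL, n_restarts = 100,
                             method = c("kmeans", "hclust")) {
  method <- match.arg(method)
  if (k < 1) stop_("k must be >= 1")
  if (k > nrow(z)) stop_("k = %d exceeds the number of proteins (%d)", k, nrow(z))
  if (is.null(rownames(z))) rownames(z) <- seq_len(nrow(z))
  if (method == "hclust") {
    hc <- stats::hclust(stats::dist(z), method = "average")
    cl <- stats::cutree(hc, k = k)
    cent <- do.call(rbind, lapply(seq_len(k), function(j)
      colMeans(z[cl == j, , drop = FALSE])))
    tw <- sum(vapply(seq_len(k), function(j) {
      sub <- z[cl == j, , drop = FALSE]
      sum(sweep(sub, 2, colMeans(sub))^2)
    }, numeric(1)))
    fit <- list(cluster = cl, centers = cent, tot.withinss = tw)
  } else {
    fit <- with_seed(seed, {
      best <- NULL
      for (i in seq_len(n_restarts)) {
        init <- kmeanspp_centers(z, k)
        km <- suppressWarnings(
          stats::kmeans(z, centers = init, iter.max = 100))
        if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
      }
      best
    })
  }
  # stable renumbering: order centroids by average-linkage dendrogram
  ord <- if (k > 2) {
    stats::hclust(stats::dist(fit$centers), method = "average")$order
  } else seq_len(k)
  relab <- match(seq_len(k), ord)
  cl <- relab[fit$cluster]
  names(cl) <- rownames(z)
  centroids <- fit$centers[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  structure(list(
    cluster = cl,
    centroids = centroids,
    sizes = as.integer(table(factor(cl, levels = seq_len(k)))),
    tot_withinss = fit$tot.withinss,
    labels = NULL
  ), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d proteins in %d clusters (sizes: %s)\n",
              length(x$cluster), nrow(x$centroids),
              paste(x$sizes, collapse = ", ")))
  if (!is.null(x$labels))
    cat("  labels:", paste(sprintf("%d=%s", seq_along(x$labels), x$labels),
                           collapse = ", "), "\n")
  invisible(x)
}

# label one centroid over the six ordered gradient fractions
label_centroid <- function(centroid, eps = 1e-8) {
  stopifnot(all(GRADIENT_FRACTIONS %in% names(centroid)))
  chrom <- c("chromatome_w1", "chromatome_w2", "chromatome_w3")
  at_max <- names(centroid)[centroid >= max(centroid) - eps]
  if (all(at_max %in% chrom) &&
      centroid["nuclei"] < mean(centroid) &&
      centroid["cytoplasm"] < mean(centroid))
    return("chromatome-enriched")
  top <- names(centroid)[which.max(centroid)]
  switch(top,
         nuclei = "nucleoplasmic",
         cytoplasm = "cytoplasmic",
         whole_cell = "whole-cell",
         "mixed")
}

#' Differential fraction analysis and profile-based chromatome definition
#'
#' The six-fraction pipeline: one-way permutation-FDR ANOVA over the
#' gradient fraction groups, z-scoring of the per-fraction mean profiles of
#' significant proteins, and restarted k-means clustering (default k = 9,
#' the cluster count observed in the reference six-fraction analysis). Each
#' cluster is auto-labelled from its centroid: it is "chromatome-enriched"
#' iff the centroid maxima lie only in the chromatin-wash coordinates while
#' its nuclei and cytoplasm coordinates sit below the centroid mean. The
#' union of chromatome-enriched clusters is returned as the profile-based
#' high-confidence chromatome.
#'
#' @param mat A log2 [intensity_matrix()] over the six gradient fractions
#'   (normally imputed first).
#' @param design A [sample_design()] containing all six gradient fractions.
#' @param k Number of clusters (default 9).
#' @param config A [test_config()] for the ANOVA (`fdr`, permutations, seed).
#' @param min_fc Minimal linear fold change for ANOVA significance
#'   (default 1.5).
#' @param seed Clustering seed.
#' @param n_restarts k-means restarts.
#' @return List with `anova` (a `differential_result`), `clusters` (a
#'   `cluster_assignment` with `labels`), `z` (the z-scored profile matrix)
#'   and `high_confidence` (protein ids in chromatome-enriched clusters).
#' @export
classify_fractions <- function(mat, design, k = 9, config = test_config(),
                               min_fc = 1.5, seed = 1, n_restarts = 100) {
  d <- align_design(mat, design)
  missing_fr <- setdiff(GRADIENT_FRACTIONS, unique(d$fraction))
  if (length(missing_fr))
    stop_("design lacks gradient fraction(s): %s",
          paste(missing_fr, collapse = ", "))
  res <- multi_sample_anova(mat, design, groups = as.list(GRADIENT_FRACTIONS),
                            config = config, min_fc = min_fc)
  sig_ids <- res$protein_id[res$significant]
  if (!length(sig_ids)) {
    return(list(anova = res, clusters = NULL, z = NULL,
                high_confidence = character(0)))
  }
  gm <- group_means(mat[sig_ids, ], design, by = "fraction")
  gm <- gm[, GRADIENT_FRACTIONS, drop = FALSE]
  z <- zscore_rows(gm)
  cl <- cluster_profiles(z, k = min(k, nrow(z)), seed = seed,
                         n_restarts = n_restarts)
  cl$labels <- apply(cl$centroids, 1, function(ce) {
    names(ce) <- colnames(z); label_centroid(ce)
  })
  hc_clusters <- which(cl$labels == "chromatome-enriched")
  hc <- names(cl$cluster)[cl$cluster %in% hc_clusters]
  list(anova = res, clusters = cl, z = z, high_confidence = hc)
}

#' Per-cell-line high-confidence chromatome
#'
#' Defines high-confidence chromatin binders as proteins significantly
#' enriched in the chromatome over the matched total proteome by a plain
#' two-sample Student t test: membership requires raw `p < p_threshold` and
#' chromatome mean minus proteome mean of at least `log2(min_fc)` (the rule
#' is one-directional; chromatin-depleted proteins never qualify).
#'
#' @param chromatome,proteome Log2 [intensity_matrix()] objects over shared
#'   proteins (normally imputed).
#' @param design A [sample_design()] covering both layers.
#' @param p_threshold Raw p-value threshold (default 0.05).
#' @param min_fc Minimal linear chromatome/proteome fold change
#'   (default 1.5).
#' @param condition Optional condition label to restrict both layers to.
#' @return A `high_confidence_set`: `proteins` (member ids), `result` (the
#'   per-protein test table) and `thresholds`.
#' @export
define_high_confidence <- function(chromatome, proteome, design,
                                   p_threshold = 0.05, min_fc = 1.5,
                                   condition = NULL) {
  assert_log2(chromatome, "define_high_confidence")
  assert_log2(proteome, "define_high_confidence")
  shared <- intersect(protein_ids(chromatome), protein_ids(proteome))
  if (!length(shared)) stop_("no shared proteins between layers")
  dc <- align_design(chromatome, design)
  dp <- align_design(proteome, design)
  if (!is.null(condition)) {
    if (!condition %in% dc$condition || !condition %in% dp$condition)
      stop_("condition '%s' absent from one of the layers", condition)
    dc <- dc[dc$condition == condition, , drop = FALSE]
    dp <- dp[dp$condition == condition, , drop = FALSE]
  } else if (!setequal(unique(dc$condition), unique(dp$condition))) {
    stop_("layers cover different conditions; pass `condition` explicitly")
  }
  x <- cbind(chromatome$values[shared, dc$sample_id, drop = FALSE],
             proteome$values[shared, dp$sample_id, drop = FALSE])
  na <- nrow(dc); nb <- nrow(dp)
  st <- sam_stat(x, seq_len(na), na + seq_len(nb), s0 = 0)
  p <- 2 * stats::pt(abs(st$t), df = st$df, lower.tail = FALSE)
  p[st$df < 2 | is.na(st$se)] <- NA_real_
  member <- !is.na(p) & p < p_threshold & st$diff >= log2(min_fc)
  result <- data.frame(
    protein_id = shared,
    mean_chromatome = st$mean_a, mean_proteome = st$mean_b,
    difference = st$diff, t = st$t, p = p, member = member,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    proteins = shared[member],
    result = result,
    thresholds = list(p_threshold = p_threshold, min_fc = min_fc,
                      condition = condition)
  ), class = "high_confidence_set")
}

#' @export
print.high_confidence_set <- function(x, ...) {
  cat(sprintf("<high_confidence_set> %d of %d proteins (p < %g, FC >= %g)\n",
              length(x$proteins), nrow(x$result),
              x$thresholds$p_threshold, x$thresholds$min_fc))
  invisible(x)
}
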