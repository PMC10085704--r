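# Valid-value filtering, CV-based QC and Gaussian-downshift imputation.

# proteins x groups matrix of valid-value counts
valid_counts <- function(mat, design) {
  d <- align_design(mat, design)
  key <- group_key(d)
  groups <- unique(key)
  out <- vapply(groups, function(g)
    rowSums(!is.na(mat$values[, key == g, drop = FALSE])),
    numeric(nrow(mat$values)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(protein_ids(mat), groups))
  out
}

#' Filter proteins by valid values per replicate group
#'
#' Keeps proteins with at least `min_valid` quantified (non-missing) values
#' in a replicate group. With `scope = "any_group"` one passing group
#' suffices (the convention for two-group tests); `"all_groups"` requires
#' every group to pass. The default `min_valid = 2` implements the rule that
#' proteins with fewer than 2 of 3 valid values are removed.
#'
#' @param mat A log2 [intensity_matrix()].
#' @param design A [sample_design()].
#' @param min_valid Minimum quantified values per group.
#' @param scope `"any_group"` or `"all_groups"`.
#' @return The filtered `intensity_matrix`.
#' @export
filter_min_valid <- function(mat, design, min_valid = 2,
                             scope = c("any_group", "all_groups")) {
  scope <- match.arg(scope)
  d <- align_design(mat, design)
  sizes <- table(group_key(d))
  if (any(sizes < min_valid))
    stop_("group(s) smaller than min_valid=%d: %s", min_valid,
          paste(names(sizes)[sizes < min_valid], collapse = ", "))
  vc <- valid_counts(mat, design)
  keep <- if (scope == "any_group") apply(vc >= min_valid, 1, any)
          else apply(vc >= min_valid, 1, all)
  mat[keep, ]
}

#' Coefficient-of-variation QC report
#'
#' Computes, per protein and replicate group, the percent coefficient of
#' variation over valid values. Intensities are back-transformed to the
#' linear scale first (CV% is a linear-scale statistic); proteins with fewer
#' than `min_valid` valid values in a group get a missing CV, never zero.
#'
#' @param mat A log2 [intensity_matrix()].
#' @param design A [sample_design()].
#' @param min_valid Minimum valid values per group for a CV to be reported.
#' @return A `qc_report` list: `cv` (proteins x groups CV% matrix),
#'   `n_valid` (counts), `sample_missing` (per-sample missing fraction) and
#'   `summary` (per group: median CV, counts with CV < 20% and < 10%).
#' @export
compute_cv <- function(mat, design, min_valid = 2) {
  assert_log2(mat, "compute_cv")
  d <- align_design(mat, design)
  key <- group_key(d)
  groups <- unique(key)
  lin <- 2^mat$values
  cv <- vapply(groups, function(g) {
    sub <- lin[, key == g, drop = FALSE]
    n <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    s <- apply(sub, 1, stats::sd, na.rm = TRUE)
    out <- 100 * s / m
    out[n < min_valid] <- NA_real_
    out
  }, numeric(nrow(lin)))
  if (is.null(dim(cv))) cv <- matrix(cv, nrow = 1,
                                     dimnames = list(protein_ids(mat), groups))
  summ <- data.frame(
    group = groups,
    n_reported = colSums(!is.na(cv)),
    median_cv = apply(cv, 2, stats::median, na.rm = TRUE),
    n_below_20 = colSums(cv < 20, na.rm = TRUE),
    n_below_10 = colSums(cv < 10, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    cv = cv,
    n_valid = valid_counts(mat, design),
    sample_missing = colMeans(is.na(mat$values)),
    summary = summ
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  print(x$summary)
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  df <- data.frame(protein_id = rownames(x$cv), stringsAsFactors = FALSE)
  cbind(df, as.data.frame(x$cv, check.names = FALSE))
}

#' Gaussian-downshift imputation of missing values
#'
#' Replaces each missing cell of column `j` with a draw from
#' `Normal(mean_j - downshift * sd_j, (width * sd_j)^2)`, where `mean_j` and
#' `sd_j` are computed over the observed values of that column. This models
#' left-censored (MNAR) missingness: missing proteins are assumed to sit
#' below the detection limit. Defaults are width 0.2 and downshift 1.8
#' standard deviations. Observed cells are never altered.
#'
#' @param mat A log2 [intensity_matrix()]; every column needs >= 2 observed
#'   values.
#' @param width Width of the imputation distribution as a fraction of the
#'   observed column SD (> 0).
#' @param downshift Downshift of the imputation mean in observed column SDs
#'   (>= 0).
#' @param seed Integer seed for reproducible draws, or `NULL`.
#' @return An `intensity_matrix` with no missing values.
#' @export
impute_gaussian_downshift <- function(mat, width = 0.2, downshift = 1.8,
                                      seed = NULL) {
  assert_log2(mat, "imputation")
  if (width <= 0) stop_("width must be > 0")
  if (downshift < 0) stop_("downshift must be >= 0")
  v <- mat$values
  n_obs <- colSums(!is.na(v))
  if (any(n_obs < 2))
    stop_("column(s) with < 2 observed values: %s",
          paste(colnames(v)[n_obs < 2], collapse = ", "))
  with_seed(seed, {
    for (j in seq_len(ncol(v))) {
      miss <- is.na(v[, j])
      if (!any(miss)) next
      m <- mean(v[!miss, j])
      s <- stats::sd(v[!miss, j])
      v[miss, j] <- stats::rnorm(sum(miss), m - downshift * s, width * s)
    }
    out <- mat
    out$values <- v
    out
  })
}
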