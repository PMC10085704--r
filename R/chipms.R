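# ChIP-MS: differential enrichment versus IgG and bait-normalized
# complex stoichiometry.

#' ChIP-MS differential enrichment versus IgG control
#'
#' Filters out proteins identified (quantified) fewer than `min_identified`
#' times within a triplicate set, imputes remaining missing values by
#' Gaussian downshift, and runs the s0-moderated permutation-FDR test of the
#' specific pulldown against the IgG control. The "enriched" call requires
#' significance at the configured FDR plus a positive log2 fold change of at
#' least `fc_threshold_log2` (default 1). Proteins never detected in the
#' control before imputation are flagged `control_absent`.
#'
#' @param mat A log2 [intensity_matrix()] of LFQ intensities with pulldown
#'   and IgG columns.
#' @param design A [sample_design()] with fractions `"pulldown"` and
#'   `"igg"`.
#' @param condition Optional condition to restrict to.
#' @param config A [test_config()] (defaults: s0 = 1, FDR 5%, two-sided,
#'   log2 FC cutoff 1).
#' @param min_identified Minimal valid values per triplicate set
#'   (default 2); a protein passing in either group is kept.
#' @param impute_seed Seed for the imputation draws.
#' @param width,downshift Imputation parameters (defaults 0.2 / 1.8).
#' @return A `differential_result` with an extra `enriched` and
#'   `control_absent` column.
#' @export
chipms_differential <- function(mat, design, condition = NULL,
                                config = test_config(),
                                min_identified = 2, impute_seed = NULL,
                                width = 0.2, downshift = 1.8) {
  d <- align_design(mat, design)
  if (!is.null(condition)) {
    d <- d[d$condition == condition, , drop = FALSE]
    mat <- mat[, d$sample_id]
  }
  if (!"igg" %in% d$fraction) stop_("design lacks an IgG control group")
  if (!"pulldown" %in% d$fraction) stop_("design lacks a pulldown group")
  dd <- sample_design(d$sample_id, d$fraction, d$condition, d$replicate)
  filtered <- filter_min_valid(mat, dd, min_valid = min_identified,
                               scope = "any_group")
  control_absent <- rowSums(!is.na(
    filtered$values[, design_samples(dd, fraction = "igg"), drop = FALSE])) == 0
  imputed <- impute_gaussian_downshift(filtered, width = width,
                                       downshift = downshift,
                                       seed = impute_seed)
  res <- sam_ttest(imputed, dd, group_a = "pulldown", group_b = "igg",
                   config = config)
  res$enriched <- res$significant & res$difference >= config$fc_threshold_log2
  res$control_absent <- control_absent[res$protein_id]
  attr(res, "test") <- "chipms pulldown vs IgG"
  res
}

#' Bait-normalized complex stoichiometry
#'
#' Per pulldown replicate, the log2 iBAQ of each complex member is
#' normalized to the bait (member minus bait); per condition the ratios are
#' averaged on the log2 scale (a geometric mean in linear space) and
#' back-transformed to a linear stoichiometry, with the SD across replicates
#' reported. The bait's stoichiometry is exactly 1 in every condition by
#' construction. Replicates in which the bait was not quantified are dropped
#' with a warning.
#'
#' @param mat A log2 [intensity_matrix()] of iBAQ values.
#' @param design A [sample_design()]; only `"pulldown"` columns are used.
#' @param bait Protein id of the bait.
#' @param members Character vector of complex-member ids (the bait is always
#'   included).
#' @return A `stoichiometry_table` data frame: per member x condition the
#'   mean log2 ratio to the bait, its SD across replicates, the linear
#'   stoichiometry and the number of replicates used.
#' @export
stoichiometry <- function(mat, design, bait, members) {
  assert_log2(mat, "stoichiometry")
  if (!bait %in% protein_ids(mat)) stop_("bait '%s' not in the matrix", bait)
  members <- union(bait, members)
  miss <- setdiff(members, protein_ids(mat))
  if (length(miss))
    stop_("member(s) not in the matrix: %s", paste(miss, collapse = ", "))
  d <- align_design(mat, design)
  d <- d[d$fraction == "pulldown", , drop = FALSE]
  if (!nrow(d)) stop_("no pulldown samples in the design")
  bait_ok <- !is.na(mat$values[bait, d$sample_id])
  if (!any(bait_ok)) stop_("bait '%s' quantified in no pulldown replicate", bait)
  if (any(!bait_ok))
    warn_("dropping %d replicate(s) without bait quantification: %s",
          sum(!bait_ok), paste(d$sample_id[!bait_ok], collapse = ", "))
  d <- d[bait_ok, , drop = FALSE]
  rows <- list()
  for (cc in unique(d$condition)) {
    cs <- d$sample_id[d$condition == cc]
    ratios <- mat$values[members, cs, drop = FALSE] -
      matrix(mat$values[bait, cs], length(members), length(cs), byrow = TRUE)
    m <- rowMeans(ratios, na.rm = TRUE)
    s <- apply(ratios, 1, stats::sd, na.rm = TRUE)
    n <- rowSums(!is.na(ratios))
    rows[[cc]] <- data.frame(
      protein_id = members, condition = cc,
      log2_ratio_to_bait = m, sd_log2_ratio = s,
      stoichiometry = 2^m, n_replicates = n,
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bait") <- bait
  class(out) <- c("stoichiometry_table", "data.frame")
  out
}

#' @export
print.stoichiometry_table <- function(x, ...) {
  cat(sprintf("<stoichiometry_table> bait %s, %d members x %d condition(s)\n",
              attr(x, "bait"), length(unique(x$protein_id)),
              length(unique(x$condition))))
  print(as.data.frame(x))
  invisible(x)
}
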