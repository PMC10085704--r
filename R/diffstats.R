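# s0-moderated two-sample tests and one-way ANOVA with permutation-based
# FDR (SAM-style), paired proteome-normalized tests, BH adjustment.

#' Test configuration
#'
#' @param s0 Non-negative moderation constant added to the standard-error
#'   denominator of the t statistic (SAM convention); default 1. Penalizes
#'   proteins whose significance rests only on a tiny variance.
#' @param n_permutations Number of label permutations for the FDR estimate;
#'   if the number of distinct assignments is smaller, all are enumerated.
#' @param fdr Target FDR level (default 0.05).
#' @param sides `"two"` (default) or `"one"` (alternative: group A > group B).
#' @param fc_threshold_log2 Minimal absolute log2 difference required for a
#'   significance call (default 1, i.e. fold change >= 2).
#' @param seed Seed for random permutations, or `NULL`.
#' @return A `test_config` list.
#' @export
test_config <- function(s0 = 1, n_permutations = 250, fdr = 0.05,
                        sides = c("two", "one"), fc_threshold_log2 = 1,
                        seed = NULL) {
  sides <- match.arg(sides)
  if (s0 < 0) stop_("s0 must be >= 0")
  if (fdr <= 0 || fdr >= 1) stop_("fdr must be in (0, 1)")
  if (n_permutations < 1) stop_("n_permutations must be >= 1")
  structure(list(s0 = s0, n_permutations = as.integer(n_permutations),
                 fdr = fdr, sides = sides,
                 fc_threshold_log2 = fc_threshold_log2, seed = seed),
            class = "test_config")
}

# NA-aware row means/variances over a column subset
row_stats <- function(x, idx) {
  sub <- x[, idx, drop = FALSE]
  n <- rowSums(!is.na(sub))
  m <- rowMeans(sub, na.rm = TRUE)
  m[n == 0] <- NA_real_
  ctr <- sub - m
  v <- rowSums(ctr * ctr, na.rm = TRUE) / (n - 1)
  v[n < 2] <- NA_real_
  list(n = n, mean = m, var = v)
}

# moderated two-sample statistic for a given A/B column split
sam_stat <- function(x, ia, ib, s0) {
  a <- row_stats(x, ia)
  b <- row_stats(x, ib)
  sp2 <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / (a$n + b$n - 2)
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  diff <- a$mean - b$mean
  d <- diff / (se + s0)
  # classical (unmoderated) t for the raw p value
  t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  list(mean_a = a$mean, mean_b = b$mean, diff = diff, se = se, d = d, t = t,
       df = a$n + b$n - 2, n_a = a$n, n_b = b$n)
}

# SAM-style permutation FDR over cutoffs on the test statistic.
# s_obs: observed statistics (already |d| for two-sided, signed d or F
# otherwise); s_perm: proteins x permutations matrix of null statistics.
# Returns per-protein q: for each candidate cutoff c (the observed statistic
# values), FDRhat(c) = mean permuted #{>= c} / observed #{>= c}, capped at 1;
# a protein's q is the smallest FDRhat over cutoffs it attains (c <= its
# statistic), which is automatically non-increasing in the statistic.
perm_fdr_q <- function(s_obs, s_perm) {
  q <- rep(NA_real_, length(s_obs))
  ok <- is.finite(s_obs)
  if (!any(ok)) return(q)
  so <- sort(s_obs[ok])
  cuts <- unique(so)
  sp <- sort(s_perm[is.finite(s_perm)])
  nperm <- ncol(s_perm)
  obs_ge <- length(so) - findInterval(cuts, so, left.open = TRUE)
  perm_ge <- length(sp) - findInterval(cuts, sp, left.open = TRUE)
  fdr_hat <- pmin(1, (perm_ge / nperm) / obs_ge)
  q_cut <- cummin(fdr_hat)
  q[ok] <- q_cut[match(s_obs[ok], cuts)]
  q
}

# resolve a group spec (sample ids, condition label, or fraction label) to
# sample ids of `mat`
resolve_group <- function(mat, design, spec) {
  d <- align_design(mat, design)
  if (all(spec %in% d$sample_id)) return(intersect(d$sample_id, spec))
  if (all(spec %in% d$condition)) return(d$sample_id[d$condition %in% spec])
  if (all(spec %in% d$fraction)) return(d$sample_id[d$fraction %in% spec])
  stop_("cannot resolve group '%s' to sample ids, conditions or fractions",
        paste(spec, collapse = ","))
}

# Distinct A-label assignments over n columns (choose na as group A);
# exhaustive if feasible, else random (seeded). The observed assignment
# (1..na) reproduces the observed statistics exactly and is excluded from
# the null, as is its complement when the statistic is two-sided (|d| is
# invariant under swapping the groups); keeping them would floor every FDR
# estimate at 2 / n_assignments.
label_assignments <- function(n, na, n_permutations, seed, two_sided = TRUE) {
  obs <- seq_len(na)
  comp <- if (n - na == na) sort(setdiff(seq_len(n), obs)) else NULL
  is_identity <- function(a) {
    identical(a, obs) || (two_sided && !is.null(comp) && identical(a, comp))
  }
  if (choose(n, na) <= n_permutations + 2) {
    all <- utils::combn(n, na, simplify = FALSE)
    Filter(function(a) !is_identity(a), all)
  } else {
    with_seed(seed, {
      out <- vector("list", n_permutations)
      i <- 0L
      while (i < n_permutations) {
        a <- sort(sample.int(n, na))
        if (is_identity(a)) next
        i <- i + 1L
        out[[i]] <- a
      }
      out
    })
  }
}

new_differential_result <- function(df, config, test) {
  attr(df, "config") <- config
  attr(df, "test") <- test
  class(df) <- c("differential_result", "data.frame")
  df
}

#' @export
print.differential_result <- function(x, ...) {
  cat(sprintf("<differential_result> %s: %d proteins, %d significant\n",
              attr(x, "test"), nrow(x), sum(x$significant, na.rm = TRUE)))
  invisible(as.data.frame(x))
}

#' s0-moderated two-sample test with permutation-based FDR
#'
#' For each protein computes the moderated statistic
#' `d = (meanA - meanB) / (se + s0)` with `se` the pooled-variance two-sample
#' standard error, plus a classical Student t p value. The q value is a
#' SAM-style permutation FDR: group labels are resampled (all distinct
#' assignments when their number does not exceed `n_permutations`, otherwise
#' that many random ones; the observed assignment and, for two-sided
#' statistics, its mirror are excluded from the null), and for every
#' candidate cutoff on `|d|`
#' (two-sided) or signed `d` (one-sided) the estimated FDR is the mean
#' permuted exceedance count over the observed exceedance count, capped at 1;
#' each protein receives the smallest estimate over cutoffs it attains.
#' A protein is called significant when `q <= fdr` and its absolute log2
#' difference reaches `fc_threshold_log2`.
#'
#' @param mat A log2 [intensity_matrix()] (normally after imputation).
#' @param design A [sample_design()].
#' @param group_a,group_b Group specs: vectors of sample ids, a condition
#'   label, or a fraction label.
#' @param config A [test_config()].
#' @return A `differential_result` data frame with columns `protein_id`,
#'   `mean_a`, `mean_b`, `difference`, `se`, `d`, `p`, `q`, `significant`.
#' @export
sam_ttest <- function(mat, design, group_a, group_b, config = test_config()) {
  assert_log2(mat, "sam_ttest")
  ia_id <- resolve_group(mat, design, group_a)
  ib_id <- resolve_group(mat, design, group_b)
  if (length(intersect(ia_id, ib_id)))
    stop_("groups overlap: %s", paste(intersect(ia_id, ib_id), collapse = ", "))
  x <- mat$values[, c(ia_id, ib_id), drop = FALSE]
  na <- length(ia_id); nb <- length(ib_id)
  if (choose(na + nb, na) < 2) stop_("fewer than 2 distinct label permutations")
  obs <- sam_stat(x, seq_len(na), na + seq_len(nb), config$s0)

  assigns <- label_assignments(na + nb, na, config$n_permutations, config$seed,
                               two_sided = config$sides == "two")
  if (length(assigns) < 2) stop_("fewer than 2 distinct label permutations")
  d_perm <- vapply(assigns, function(ia) {
    sam_stat(x, ia, setdiff(seq_len(na + nb), ia), config$s0)$d
  }, numeric(nrow(x)))
  if (is.null(dim(d_perm))) d_perm <- matrix(d_perm, nrow = nrow(x))

  if (config$sides == "two") {
    q <- perm_fdr_q(abs(obs$d), abs(d_perm))
    p <- 2 * stats::pt(abs(obs$t), df = obs$df, lower.tail = FALSE)
  } else {
    q <- perm_fdr_q(obs$d, d_perm)
    p <- stats::pt(obs$t, df = obs$df, lower.tail = FALSE)
  }
  p[obs$df < 2 | is.na(obs$se)] <- NA_real_
  fc_ok <- if (config$sides == "two") abs(obs$diff) >= config$fc_threshold_log2
           else obs$diff >= config$fc_threshold_log2
  sig <- !is.na(q) & q <= config$fdr & fc_ok
  df <- data.frame(
    protein_id = rownames(x),
    mean_a = obs$mean_a, mean_b = obs$mean_b,
    difference = obs$diff, se = obs$se, d = obs$d,
    p = p, q = q, significant = sig,
    row.names = NULL, stringsAsFactors = FALSE
  )
  new_differential_result(df, config, sprintf(
    "sam_ttest %s vs %s", paste(group_a, collapse = ","),
    paste(group_b, collapse = ",")))
}

#' Paired proteome-normalized chromatome test
#'
#' Implements testing of "normalized chromatomes": per protein, condition and
#' replicate, the pairwise difference chromatome log2 minus the matched
#' proteome log2 is computed (replicate i of a condition in one layer pairs
#' with replicate i in the other); [sam_ttest()] is then applied between two
#' conditions on the difference matrix, so a hit is a chromatome change not
#' explained by a proteome change.
#'
#' @param chromatome,proteome Log2 [intensity_matrix()] objects over the same
#'   proteins.
#' @param design A [sample_design()] covering both layers (chromatome columns
#'   with a chromatin fraction label, proteome columns with `"proteome"`).
#' @param condition_a,condition_b Condition labels to contrast.
#' @param config A [test_config()].
#' @return A `differential_result` on the difference scale.
#' @export
paired_normalized_ttest <- function(chromatome, proteome, design,
                                    condition_a, condition_b,
                                    config = test_config()) {
  assert_log2(chromatome, "paired_normalized_ttest")
  assert_log2(proteome, "paired_normalized_ttest")
  shared <- intersect(protein_ids(chromatome), protein_ids(proteome))
  if (!length(shared)) stop_("no shared proteins between layers")
  dc <- align_design(chromatome, design)
  dp <- align_design(proteome, design)
  conds <- c(condition_a, condition_b)
  cols <- c(); cvec <- c(); rvec <- c()
  diffs <- NULL
  for (cc in conds) {
    cs <- dc$sample_id[dc$condition == cc]
    ps <- dp$sample_id[dp$condition == cc]
    if (!length(cs) || length(cs) != length(ps))
      stop_("condition '%s': unequal replicate counts between layers (%d vs %d)",
            cc, length(cs), length(ps))
    cs <- cs[order(dc$replicate[match(cs, dc$sample_id)])]
    ps <- ps[order(dp$replicate[match(ps, dp$sample_id)])]
    block <- chromatome$values[shared, cs, drop = FALSE] -
      proteome$values[shared, ps, drop = FALSE]
    newcols <- paste("normdiff", cc, seq_along(cs), sep = "_")
    colnames(block) <- newcols
    diffs <- cbind(diffs, block)
    cols <- c(cols, newcols); cvec <- c(cvec, rep(cc, length(cs)))
    rvec <- c(rvec, seq_along(cs))
  }
  dmat <- intensity_matrix(diffs, scale = "log2")
  ddesign <- sample_design(cols, "chromatome", cvec, rvec)
  res <- sam_ttest(dmat, ddesign, condition_a, condition_b, config)
  attr(res, "test") <- sprintf("paired_normalized_ttest %s vs %s",
                               condition_a, condition_b)
  res
}

#' Multi-sample one-way ANOVA with permutation FDR and fold-change filter
#'
#' One-way ANOVA F statistic per protein across three or more groups, with
#' the same permutation FDR estimator as [sam_ttest()] applied to cutoffs on
#' F (group labels shuffled across all samples). A protein is called
#' significant when `q <= fdr` and the largest absolute pairwise difference
#' of group means reaches `log2(min_fc)` (minimal 1.5-fold change by
#' default).
#'
#' @param mat A log2 [intensity_matrix()] (normally after imputation).
#' @param design A [sample_design()].
#' @param groups Optional list/vector of group specs (see [sam_ttest()]);
#'   default: conditions if several, otherwise fractions.
#' @param config A [test_config()] (`fdr`, `n_permutations`, `seed` used).
#' @param min_fc Minimal linear fold change between the extreme group means
#'   (default 1.5).
#' @return A `differential_result` with columns `F`, `p`, `q`,
#'   `max_abs_diff`, `significant` and one mean column per group.
#' @export
multi_sample_anova <- function(mat, design, groups = NULL,
                               config = test_config(), min_fc = 1.5) {
  assert_log2(mat, "multi_sample_anova")
  d <- align_design(mat, design)
  if (is.null(groups)) {
    groups <- if (length(unique(d$condition)) > 1) unique(d$condition)
              else unique(d$fraction)
  }
  gcols <- lapply(groups, function(g) resolve_group(mat, design, g))
  if (length(gcols) < 3) stop_("multi_sample_anova needs >= 3 groups")
  sizes <- lengths(gcols)
  if (any(sizes < 2)) stop_("every group needs >= 2 replicates")
  gl <- rep(seq_along(gcols), sizes)
  x <- mat$values[, unlist(gcols), drop = FALSE]
  k <- length(gcols)

  fstat <- function(xs, labels) {
    ms <- vapply(seq_len(k), function(j) {
      s <- row_stats(xs, which(labels == j)); c(s$n, s$mean, s$var)
    }, numeric(3 * nrow(xs)))
    nr <- nrow(xs)
    n_g <- ms[seq_len(nr), , drop = FALSE]
    m_g <- ms[nr + seq_len(nr), , drop = FALSE]
    v_g <- ms[2 * nr + seq_len(nr), , drop = FALSE]
    N <- rowSums(n_g)
    grand <- rowSums(n_g * m_g) / N
    ssb <- rowSums(n_g * (m_g - grand)^2)
    ssw <- rowSums((n_g - 1) * v_g, na.rm = TRUE)
    f <- (ssb / (k - 1)) / (ssw / (N - k))
    f[ssb == 0] <- 0  # no between-group variation (0/0 on constant rows)
    list(f = f, means = m_g, n = n_g, N = N)
  }
  obs <- fstat(x, gl)
  bad <- apply(obs$n < 2, 1, any)
  f <- obs$f
  f[bad] <- NA_real_
  p <- stats::pf(f, k - 1, obs$N - k, lower.tail = FALSE)
  rng <- apply(obs$means, 1, function(m) diff(range(m)))
  # a shuffle that merely renames whole groups reproduces F and is not a
  # null draw; resample such shuffles (cf. the identity-assignment exclusion
  # in label_assignments)
  same_partition <- function(labels) {
    tab <- table(gl, labels)
    all(rowSums(tab > 0) == 1)
  }
  f_perm <- with_seed(config$seed, {
    vapply(seq_len(config$n_permutations), function(i) {
      repeat {
        labels <- sample(gl)
        if (!same_partition(labels)) break
      }
      fstat(x, labels)$f
    }, numeric(nrow(x)))
  })
  if (is.null(dim(f_perm))) f_perm <- matrix(f_perm, nrow = nrow(x))
  f_perm[bad, ] <- NA_real_
  q <- perm_fdr_q(f, f_perm)
  sig <- !is.na(q) & q <= config$fdr & rng >= log2(min_fc)
  means <- obs$means
  colnames(means) <- paste0("mean_", vapply(groups, function(g)
    paste(g, collapse = "."), ""))
  df <- data.frame(protein_id = rownames(x), means,
                   F = f, p = p, q = q, max_abs_diff = rng,
                   significant = sig,
                   row.names = NULL, stringsAsFactors = FALSE,
                   check.names = FALSE)
  cfg <- config; cfg$min_fc <- min_fc
  new_differential_result(df, cfg, sprintf("anova over %d groups", k))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p values in \[0, 1\] (`NA` allowed, passed through).
#' @return Adjusted q values: monotone step-up minima of `p * m / rank`,
#'   capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_("p values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(q)
  o <- order(p[ok], decreasing = TRUE)
  q[ok[o]] <- pmin(1, cummin(p[ok][o] * m / seq(m, 1)))
  q
}
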