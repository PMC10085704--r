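# In-code fixtures and independent oracles shared across test files.

# tiny intensity matrix from a plain numeric matrix
im <- function(values, ids = NULL, samples = NULL, scale = "log2") {
  if (is.null(ids)) ids <- sprintf("P%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(ids, samples)
  intensity_matrix(values, scale = scale)
}

# two-group triplicate design (a1..a3 vs b1..b3)
design_ab <- function(fraction_a = "chromatome", fraction_b = "proteome",
                      condition = "naive") {
  sample_design(c("s1", "s2", "s3", "s4", "s5", "s6"),
                rep(c(fraction_a, fraction_b), each = 3),
                condition, rep(1:3, 2))
}

# two-condition design within one fraction
design_cond <- function(conds = c("naive", "formative"), nr = 3,
                        fraction = "chromatome") {
  n <- length(conds) * nr
  sample_design(sprintf("s%d", seq_len(n)), fraction,
                rep(conds, each = nr), rep(seq_len(nr), length(conds)))
}

# Independent brute-force oracle for the SAM permutation q values on an
# nA-vs-nB design: explicit loops, no shared code with the implementation.
oracle_sam_q <- function(x, na, nb, s0, sides = "two") {
  n <- na + nb
  dstat <- function(cols_a) {
    cols_b <- setdiff(seq_len(n), cols_a)
    d <- numeric(nrow(x))
    for (i in seq_len(nrow(x))) {
      a <- x[i, cols_a]; b <- x[i, cols_b]
      sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
        (length(a) + length(b) - 2)
      se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
      d[i] <- (mean(a) - mean(b)) / (se + s0)
    }
    d
  }
  splits <- combn(n, na, simplify = FALSE)
  obs_split <- seq_len(na)
  comp_split <- sort(setdiff(seq_len(n), obs_split))
  keep <- vapply(splits, function(s) {
    !(identical(s, obs_split) ||
        (sides == "two" && na == nb && identical(s, comp_split)))
  }, logical(1))
  splits <- splits[keep]
  stat <- function(d) if (sides == "two") abs(d) else d
  s_obs <- stat(dstat(obs_split))
  s_perm <- sapply(splits, function(s) stat(dstat(s)))
  cutoffs <- sort(unique(s_obs))
  fdr_at <- numeric(length(cutoffs))
  for (j in seq_along(cutoffs)) {
    c0 <- cutoffs[j]
    obs_ge <- sum(s_obs >= c0)
    perm_ge <- mean(apply(s_perm, 2, function(col) sum(col >= c0)))
    fdr_at[j] <- min(1, perm_ge / obs_ge)
  }
  q <- numeric(length(s_obs))
  for (i in seq_along(s_obs)) {
    q[i] <- min(fdr_at[cutoffs <= s_obs[i]])
  }
  q
}

# closed-form hypergeometric probability via log-binomials (independent of
# stats::dhyper, which the implementation uses)
lchoose_dhyper <- function(k, K, n, N) {
  exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n))
}

oracle_hyper_p <- function(k, K, n, N, alternative) {
  lo <- max(0, n - (N - K)); hi <- min(K, n)
  dens <- vapply(lo:hi, lchoose_dhyper, numeric(1), K = K, n = n, N = N)
  if (alternative == "over") sum(dens[(lo:hi) >= k])
  else sum(dens[dens <= lchoose_dhyper(k, K, n, N) * (1 + 1e-7)])
}

# write a small GMT file, return path
write_gmt_fixture <- function(lines, path = tempfile(fileext = ".gmt")) {
  writeLines(lines, path)
  path
}
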