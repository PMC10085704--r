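test_that("the moderated statistic follows d = diff / (se + s0)", {
  a <- sqrt(1.5)
  v <- rbind(c(2 - a, 2, 2 + a, -a, 0, a),   # diff 2, pooled se 1
             c(10, 10, 10, 10, 10, 10))      # no signal at all
  mat <- im(v)
  d <- design_ab()
  res <- sam_ttest(mat, d, "chromatome", "proteome",
                   test_config(s0 = 1, seed = 1))
  expect_equal(res$difference[1], 2)
  expect_equal(res$se[1], 1)
  expect_equal(res$d[1], 1)          # 2 / (1 + 1)
  expect_equal(res$difference[2], 0)
  expect_equal(res$d[2], 0)
  expect_false(res$significant[2])
})

test_that("permutation q values equal the exhaustive brute-force oracle", {
  for (s0 in c(0, 1)) {
    for (sides in c("two", "one")) {
      set.seed(31 + s0)
      x <- matrix(rnorm(50 * 6), 50, 6)
      x[1:8, 1:3] <- x[1:8, 1:3] + 2   # some real effects
      mat <- im(x)
      res <- sam_ttest(mat, design_ab(), "chromatome", "proteome",
                       test_config(s0 = s0, sides = sides, seed = 5))
      expect_equal(res$q, oracle_sam_q(x, 3, 3, s0 = s0, sides = sides),
                   tolerance = 1e-12,
                   info = sprintf("s0=%g sides=%s", s0, sides))
    }
  }
})

test_that("q is monotone non-increasing in |d| and s0 shrinks |d|", {
  set.seed(9)
  x <- matrix(rnorm(200 * 6), 200, 6)
  x[1:30, 1:3] <- x[1:30, 1:3] + rnorm(30 * 3, 1.5)
  mat <- im(x)
  r1 <- sam_ttest(mat, design_ab(), "chromatome", "proteome",
                  test_config(s0 = 0.5, seed = 2))
  ord <- order(abs(r1$d), decreasing = TRUE)
  expect_true(all(diff(r1$q[ord]) >= -1e-12))
  r2 <- sam_ttest(mat, design_ab(), "chromatome", "proteome",
                  test_config(s0 = 2, seed = 2))
  expect_true(all(abs(r2$d) <= abs(r1$d) + 1e-12))
  # s0 = 0 recovers the classical t ordering
  r0 <- sam_ttest(mat, design_ab(), "chromatome", "proteome",
                  test_config(s0 = 0, seed = 2))
  tt <- apply(x, 1, function(row)
    abs(t.test(row[1:3], row[4:6], var.equal = TRUE)$statistic))
  expect_equal(order(abs(r0$d)), order(tt))
})

test_that("a global-null simulation keeps discoveries near zero", {
  set.seed(17)
  hits <- replicate(5, {
    x <- matrix(rnorm(400 * 6, 25, 1), 400, 6)
    res <- sam_ttest(im(x), design_ab(), "chromatome", "proteome",
                     test_config(seed = sample.int(1e6, 1)))
    sum(res$significant)
  })
  expect_lte(mean(hits) / 400, 0.05)
})

test_that("group resolution rejects overlap and degenerate permutations", {
  mat <- im(matrix(rnorm(12, 25), 2, 6))
  d <- design_ab()
  expect_error(sam_ttest(mat, d, c("s1", "s2", "s3"), c("s3", "s4"),
                         test_config()), "overlap")
  expect_error(sam_ttest(mat, d, "membrane", "proteome", test_config()),
               "cannot resolve")
})

test_that("paired normalized test isolates chromatome-only shifts", {
  d <- design_cond()
  dp <- sample_design(sprintf("p%d", 1:6), "proteome",
                      rep(c("naive", "formative"), each = 3), rep(1:3, 2))
  full <- sample_design(c(d$sample_id, dp$sample_id),
                        c(d$fraction, dp$fraction),
                        c(d$condition, dp$condition),
                        c(d$replicate, dp$replicate))
  base <- matrix(rnorm(40 * 6, 25), 40, 6)
  prot <- im(base, samples = dp$sample_id)
  # identical layers: every pairwise difference 0, nothing significant
  chrom0 <- im(base, samples = d$sample_id)
  r0 <- paired_normalized_ttest(chrom0, prot, full, "formative", "naive",
                                test_config(seed = 3))
  expect_true(all(r0$difference == 0))
  expect_false(any(r0$significant))
  # +2 chromatome-only shift in formative for protein 1, zero noise
  shifted <- base
  shifted[1, 4:6] <- shifted[1, 4:6] + 2
  r1 <- paired_normalized_ttest(im(shifted, samples = d$sample_id), prot,
                                full, "formative", "naive",
                                test_config(seed = 3))
  expect_equal(r1$difference[1], 2)
  # unequal replicate counts between layers is an error
  broken <- full[full$sample_id != "p6", ]
  expect_error(paired_normalized_ttest(chrom0, prot[, 1:5], broken,
                                       "formative", "naive"),
               "unequal replicate counts")
})

test_that("one-way F matches the closed form and aov on fixed data", {
  # groups (1,2), (2,3), (4,6): hand-computed sums of squares
  x <- c(1, 2, 2, 3, 4, 6)
  g <- rep(c("a", "b", "c"), each = 2)
  grand <- mean(x)
  ssb <- sum(2 * (tapply(x, g, mean) - grand)^2)
  ssw <- sum((x - rep(tapply(x, g, mean), each = 2))^2)
  f_closed <- (ssb / 2) / (ssw / 3)
  d3 <- sample_design(sprintf("s%d", 1:6), "chromatome",
                      rep(c("a", "b", "c"), each = 2), rep(1:2, 3))
  mat <- im(rbind(x, x * 0 + 5), samples = d3$sample_id)
  res <- multi_sample_anova(mat, d3, config = test_config(seed = 1,
                                                          n_permutations = 50))
  expect_equal(res$F[1], f_closed)
  f_aov <- summary(aov(x ~ g))[[1]]$`F value`[1]
  expect_equal(res$F[1], f_aov)
  expect_equal(res$F[2], 0)  # all groups identical
})

test_that("ANOVA applies the minimal fold-change filter", {
  # protein 1: tiny but ultra-consistent differences (max range < log2(1.5));
  # protein 2: clear 2-fold spread
  nr <- 3
  d3 <- sample_design(sprintf("s%d", 1:9), "chromatome",
                      rep(c("a", "b", "c"), each = nr), rep(1:nr, 3))
  set.seed(4)
  small <- rep(c(0, 0.2, 0.4), each = nr) + rnorm(9, sd = 0.01)
  big <- rep(c(0, 1, 2), each = nr) + rnorm(9, sd = 0.01)
  filler <- matrix(rnorm(50 * 9, 25, 1), 50, 9)
  mat <- im(rbind(small + 25, big + 25, filler), samples = d3$sample_id)
  res <- multi_sample_anova(mat, d3, config = test_config(seed = 2),
                            min_fc = 1.5)
  expect_lt(res$p[1], 1e-4)            # highly significant by p...
  expect_false(res$significant[1])     # ...but excluded by the FC filter
  expect_lt(res$max_abs_diff[1], log2(1.5))
  expect_true(res$significant[2])
  expect_error(multi_sample_anova(mat, d3, groups = list("a", "b")),
               ">= 3 groups")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(6)
  for (i in 1:5) {
    p <- runif(sample(2:50, 1))^2
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
  p_na <- c(0.01, NA, 0.5)
  expect_equal(bh_adjust(p_na)[2], NA_real_)
})
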