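make_two_layer <- function(chrom_vals, prot_vals, conds = "naive", nr = 3) {
  nc <- length(conds)
  dchrom <- sample_design(sprintf("c%d", seq_len(nc * nr)), "chromatome",
                          rep(conds, each = nr), rep(seq_len(nr), nc))
  dprot <- sample_design(sprintf("p%d", seq_len(nc * nr)), "proteome",
                         rep(conds, each = nr), rep(seq_len(nr), nc))
  full <- sample_design(c(dchrom$sample_id, dprot$sample_id),
                        c(dchrom$fraction, dprot$fraction),
                        c(dchrom$condition, dprot$condition),
                        c(dchrom$replicate, dprot$replicate))
  list(chrom = im(chrom_vals, samples = dchrom$sample_id),
       prot = im(prot_vals, samples = dprot$sample_id),
       design = full)
}

test_that("RCB is chromatome minus mean proteome, per replicate", {
  w <- make_two_layer(matrix(12, 1, 3), matrix(c(9, 10, 11), 1, 3))
  rcb <- relative_chromatin_binding(w$chrom, w$prot, w$design)
  expect_equal(unname(rcb$matrix$values[1, ]), rep(2, 3))  # 12 - mean(9,10,11)
  # identical layers with replicate-constant values -> RCB 0 everywhere
  v <- matrix(rep(rnorm(10, 25), 3), 10, 3)
  w0 <- make_two_layer(v, v)
  expect_true(all(relative_chromatin_binding(w0$chrom, w0$prot,
                                             w0$design)$matrix$values == 0))
  # location-shift invariance: adding a constant to both layers cancels
  v2 <- matrix(rnorm(30, 25), 10, 3)
  wa <- make_two_layer(v2, v2)
  wb <- make_two_layer(v2 + 3, v2 + 3)
  expect_equal(relative_chromatin_binding(wa$chrom, wa$prot,
                                          wa$design)$matrix$values,
               relative_chromatin_binding(wb$chrom, wb$prot,
                                          wb$design)$matrix$values)
})

test_that("proteome-absent proteins get the configured fallback and a flag", {
  chrom <- matrix(c(12, 13), 2, 3)
  prot <- matrix(c(10, NA), 2, 3)
  w <- make_two_layer(chrom, prot)
  r_na <- relative_chromatin_binding(w$chrom, w$prot, w$design)
  expect_true(all(is.na(r_na$matrix$values[2, ])))
  r0 <- relative_chromatin_binding(w$chrom, w$prot, w$design,
                                   proteome_absent_value = 0)
  expect_equal(unname(r0$matrix$values[2, ]), rep(0, 3))
  expect_true(r0$proteome_missing["P02", "naive"])
  expect_false(r0$proteome_missing["P01", "naive"])
})

test_that("RCB tracks chromatome-only but not proportional changes", {
  conds <- c("naive", "formative")
  set.seed(12)
  base <- matrix(rnorm(60 * 3, 25, 0.1), 60, 3)
  both <- cbind(base, base + 1.5)       # proportional +1.5 in both layers
  chromonly <- cbind(base, base + 1.5)  # chromatome-only +1.5
  protflat <- cbind(base, base)
  w_prop <- make_two_layer(both, both, conds = conds)
  w_aff <- make_two_layer(chromonly, protflat, conds = conds)
  rcb_prop <- relative_chromatin_binding(w_prop$chrom, w_prop$prot,
                                         w_prop$design)
  rcb_aff <- relative_chromatin_binding(w_aff$chrom, w_aff$prot, w_aff$design)
  gm_prop <- group_means(rcb_prop$matrix, rcb_prop$design, by = "condition")
  gm_aff <- group_means(rcb_aff$matrix, rcb_aff$design, by = "condition")
  expect_equal(mean(gm_prop[, "formative"] - gm_prop[, "naive"]), 0,
               tolerance = 0.05)
  expect_equal(mean(gm_aff[, "formative"] - gm_aff[, "naive"]), 1.5,
               tolerance = 0.05)
})

test_that("rcb_anova_cluster honours the high-confidence filter contract", {
  sim <- simulate_phase_experiment(
    sim_params(n_proteins = 200, seed = 9, n_conditions = 3,
               fraction_of_changing_proteins = 0,
               fraction_of_affinity_proteins = 0.3,
               affinity_effect_size = 2, mnar_steepness = 0))
  rcb <- relative_chromatin_binding(sim$chromatome, sim$proteome, sim$design)
  hc <- protein_ids(sim$chromatome)[1:100]
  out <- rcb_anova_cluster(rcb, hc, config = test_config(seed = 2),
                           k = 3, n_restarts = 5)
  expect_true(all(out$anova$protein_id %in% hc))
  if (!is.null(out$clusters))
    expect_true(all(names(out$clusters$cluster) %in% hc))
  expect_error(rcb_anova_cluster(rcb, "NOT_A_PROTEIN"), "no overlap")
  # null world: nothing significant
  null <- simulate_phase_experiment(
    sim_params(n_proteins = 100, seed = 10, n_conditions = 3,
               fraction_of_changing_proteins = 0,
               fraction_of_affinity_proteins = 0, mnar_steepness = 0))
  rcb0 <- relative_chromatin_binding(null$chromatome, null$proteome,
                                     null$design)
  out0 <- rcb_anova_cluster(rcb0, protein_ids(null$chromatome),
                            config = test_config(seed = 3), n_restarts = 5)
  expect_lte(sum(out0$anova$significant), 2)
})

test_that("fold-change ranking uses descending order with average ties", {
  diff <- data.frame(protein_id = c("a", "b", "c"),
                     difference = c(2, 0, -1))
  rt <- rank_by_fold_change(diff)
  expect_equal(rt$rank, c(1, 2, 3))
  expect_equal(rt$protein_id, c("a", "b", "c"))
  tie <- rank_by_fold_change(data.frame(protein_id = c("a", "b"),
                                        difference = c(1, 1)))
  expect_equal(tie$rank, c(1.5, 1.5))
  set.seed(3)
  n <- 50
  rt2 <- rank_by_fold_change(data.frame(protein_id = seq_len(n),
                                        difference = rnorm(n)))
  expect_equal(sort(rt2$rank), seq_len(n))  # a permutation of 1..n
  # reordering the table by original protein id recovers the input values
  back <- rt2[match(seq_len(n), rt2$protein_id), ]
  expect_equal(back$protein_id, seq_len(n))
})

test_that("row normalization centers every row", {
  m <- rbind(c(1, 3), c(-2, -2))
  out <- row_normalize(m)
  expect_equal(out[1, ], c(-1, 1))
  expect_equal(out[2, ], c(0, 0))
  set.seed(2)
  big <- matrix(rnorm(300), 30, 10)
  expect_true(all(abs(rowMeans(row_normalize(big))) < 1e-12))
  centered <- big - rowMeans(big)
  expect_equal(row_normalize(centered), centered)
})

test_that("pearson_correlate uses shared pairwise-complete proteins", {
  x <- setNames(rnorm(10), letters[1:10])
  expect_equal(pearson_correlate(x, x)$r, 1)
  y <- setNames(-2 * (x - mean(x)), names(x))
  expect_equal(pearson_correlate(x, y)$r, -1)
  # subsetting and NA handling
  x2 <- x; x2["a"] <- NA
  res <- pearson_correlate(x2, x, subset = letters[1:5])
  expect_equal(res$n, 4)
  expect_error(pearson_correlate(x[1:3], x[8:10]), "fewer than 3")
  # bivariate normal at rho = 0.6
  set.seed(21)
  n <- 500
  a <- rnorm(n); b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(n)
  names(a) <- names(b) <- seq_len(n)
  expect_equal(pearson_correlate(a, b)$r, 0.6, tolerance = 0.08)
})
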