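test_that("fraction simulator honours its dimensional contract and seed", {
  sim <- simulate_fraction_experiment(sim_params(n_proteins = 1000, seed = 7))
  expect_equal(dim(sim$matrix), c(1000L, 18L))
  expect_length(sim$truth$class, 1000)
  expect_equal(nrow(sim$design), 18)
  expect_setequal(unique(sim$design$fraction), GRADIENT_FRACTIONS)

  sim2 <- simulate_fraction_experiment(sim_params(n_proteins = 1000, seed = 7))
  expect_identical(sim$matrix$values, sim2$matrix$values)
  sim3 <- simulate_fraction_experiment(sim_params(n_proteins = 1000, seed = 8))
  expect_false(identical(sim$matrix$values, sim3$matrix$values))
})

test_that("zero noise and no missingness give identical replicates", {
  sim <- simulate_fraction_experiment(
    sim_params(n_proteins = 50, noise_sd = 0, mnar_steepness = 0, seed = 1))
  expect_false(anyNA(sim$matrix$values))
  for (f in GRADIENT_FRACTIONS) {
    cols <- design_samples(sim$design, fraction = f)
    expect_equal(sim$matrix$values[, cols[1]], sim$matrix$values[, cols[2]])
    expect_equal(sim$matrix$values[, cols[1]], sim$matrix$values[, cols[3]])
  }
})

test_that("missingness is intensity-dependent (MNAR)", {
  sim <- simulate_fraction_experiment(sim_params(n_proteins = 3000, seed = 11))
  base <- sim$truth$baseline_log2
  lo <- base <= quantile(base, 0.1)
  hi <- base >= quantile(base, 0.9)
  miss <- rowMeans(is.na(sim$matrix$values))
  expect_gt(mean(miss[lo]), mean(miss[hi]))
  expect_gt(mean(miss[lo]), 0.2)  # low-abundance proteins visibly censored
})

test_that("class-conditional fraction means match the declared effects", {
  prm <- sim_params(n_proteins = 4000, seed = 5, mnar_steepness = 0)
  sim <- simulate_fraction_experiment(prm)
  gm <- group_means(sim$matrix, sim$design, by = "fraction")
  for (cl in c("chromatin_binder", "cytoplasmic")) {
    rows <- sim$truth$class == cl
    # mean enrichment relative to whole_cell, averaged over class members
    rel <- rowMeans(gm[rows, c("chromatome_w1", "chromatome_w2",
                               "chromatome_w3"), drop = FALSE]) -
      gm[rows, "whole_cell"]
    want <- mean(prm$fraction_effects[cl, c("chromatome_w1", "chromatome_w2",
                                            "chromatome_w3")])
    expect_equal(mean(rel), want, tolerance = 0.05)
  }
})

test_that("phase simulator encodes affinity as chromatome minus proteome truth", {
  prm <- sim_params(n_proteins = 300, seed = 2, n_conditions = 3,
                    fraction_of_changing_proteins = 0.2,
                    condition_effect_sd = 1,
                    fraction_of_affinity_proteins = 0.2,
                    affinity_effect_sd = 1.5)
  sim <- simulate_phase_experiment(prm)
  tr <- sim$truth
  expect_identical(
    tr$condition_effects_chromatome - tr$condition_effects_proteome,
    tr$affinity_effects)
  expect_false(any(tr$is_changing & tr$is_affinity))  # disjoint subsets
  # proteome truth of pure-affinity proteins is constant across conditions
  expect_true(all(tr$condition_effects_proteome[tr$is_affinity, ] == 0))

  null <- simulate_phase_experiment(
    sim_params(n_proteins = 100, seed = 3, condition_effect_sd = 0,
               affinity_effect_sd = 0))
  expect_true(all(null$truth$condition_effects_chromatome == 0))
  expect_true(all(null$truth$condition_effects_proteome == 0))
})

test_that("simulator parameter validation rejects bad worlds", {
  expect_error(sim_params(class_fractions = c(chromatin_binder = 0.5,
                                              nucleoplasmic = 0.2,
                                              cytoplasmic = 0.2,
                                              background = 0.2)),
               "sum to 1")
  expect_error(sim_params(n_replicates = 1), "n_replicates")
  expect_error(sim_params(noise_sd = -1), "standard deviations")
  expect_error(simulate_chipms(c(SUBA = 0.5), bait = "KAT7"), "absent")
  expect_error(simulate_chipms(c(KAT7 = 2, SUBA = 0.5), bait = "KAT7"),
               "stoichiometry 1.0")
})

test_that("ChIP-MS simulator realizes exact stoichiometry at zero noise", {
  sim <- simulate_chipms(c(BAIT = 1, SUBA = 0.5, SUBB = 2),
                         bait = "BAIT", noise_sd = 0, mnar_steepness = 0,
                         n_background = 20, seed = 4)
  pd <- design_samples(sim$design, fraction = "pulldown")
  # linear iBAQ of SUBA is exactly half the bait in every replicate
  expect_equal(unname(2^sim$matrix$values["SUBA", pd] /
                        2^sim$matrix$values["BAIT", pd]),
               rep(0.5, 3))
  expect_equal(unname(sim$matrix$values["SUBB", pd] -
                        sim$matrix$values["BAIT", pd]), rep(1, 3))
  # background has equal expected intensity in pulldown and IgG
  ig <- design_samples(sim$design, fraction = "igg")
  bg <- grep("^BG", protein_ids(sim$matrix), value = TRUE)
  expect_equal(sim$matrix$values[bg, pd[1]], sim$matrix$values[bg, ig[1]])

  sim2 <- simulate_chipms(c(BAIT = 1, SUBA = 0.5, SUBB = 2),
                          bait = "BAIT", noise_sd = 0, mnar_steepness = 0,
                          n_background = 20, seed = 4)
  expect_identical(sim$matrix$values, sim2$matrix$values)
})

test_that("ground truth serializes as JSON next to the matrices", {
  sim <- simulate_fraction_experiment(sim_params(n_proteins = 20, seed = 1))
  path <- tempfile(fileext = ".json")
  write_ground_truth(sim$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$class, sim$truth$class)
  expect_equal(back$baseline_log2, sim$truth$baseline_log2, tolerance = 1e-12)
})
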