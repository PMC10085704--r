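# Seeded simulators for fractionation, phase-comparison and ChIP-MS
# experiments, with full ground truth for recovery testing.

#' Default class-by-fraction log2 enrichment effects
#'
#' Mean log2 enrichment of each latent protein class in each of the six
#' gradient fractions, relative to the whole-cell lysate. Chromatin binders
#' are enriched in the chromatin washes and depleted from the cytoplasm;
#' cytoplasmic proteins the reverse; nucleoplasmic proteins peak in the
#' nuclei fraction; background proteins are flat.
#'
#' @return Numeric matrix classes x fractions.
#' @export
default_fraction_effects <- function() {
  m <- rbind(
    chromatin_binder = c(0, -2.0, 0.5, 2.0, 2.0, 2.0),
    nucleoplasmic    = c(0, -1.0, 2.0, -1.0, -1.0, -1.0),
    cytoplasmic      = c(0,  2.0, -1.0, -2.0, -2.0, -2.0),
    background       = c(0,  0,   0,    0,    0,    0)
  )
  colnames(m) <- GRADIENT_FRACTIONS
  m
}

#' Simulation parameters
#'
#' Declares the statistical world the simulators draw from: log-normal
#' protein abundance (Gaussian in log2), latent protein classes with
#' fraction-specific enrichment, condition effects shared between proteome
#' and chromatome, chromatome-only "affinity" effects, Gaussian replicate
#' noise on the log2 scale, and intensity-dependent (MNAR) missingness with
#' probability `plogis(-mnar_steepness * (x - mnar_midpoint))` for true log2
#' intensity `x`.
#'
#' @param n_proteins Number of simulated protein groups.
#' @param class_fractions Proportions over the four latent classes
#'   (chromatin_binder, nucleoplasmic, cytoplasmic, background); must sum
#'   to 1.
#' @param baseline_log2_mean,baseline_log2_sd Hyperparameters of the log2
#'   abundance distribution.
#' @param fraction_effects Class x fraction log2 enrichment matrix, see
#'   [default_fraction_effects()].
#' @param n_conditions Number of biological conditions (phase experiments).
#' @param conditions Optional condition labels; defaults to
#'   naive/formative/primed/hESC truncated to `n_conditions`.
#' @param n_replicates Replicates per group (>= 2).
#' @param fraction_of_changing_proteins Proportion of proteins carrying true
#'   between-condition effects (both layers).
#' @param condition_effect_sd SD of true condition log2 fold changes.
#' @param condition_effect_size If non-`NULL`, condition effects are exactly
#'   `+/- condition_effect_size` (random sign) instead of Gaussian draws.
#' @param fraction_of_affinity_proteins Proportion of proteins carrying
#'   chromatome-only effects (disjoint from the changing subset).
#' @param affinity_effect_sd SD of chromatome-only log2 effects.
#' @param affinity_effect_size If non-`NULL`, affinity effects are exactly
#'   `+/- affinity_effect_size` (random sign).
#' @param chromatin_enrichment Baseline chromatome-over-proteome log2
#'   enrichment: either a per-class named vector, or a length-`n_proteins`
#'   numeric vector. Default: +2 for chromatin binders, -0.5 nucleoplasmic,
#'   -2 cytoplasmic, 0 background.
#' @param noise_sd Replicate noise SD on the log2 scale.
#' @param mnar_midpoint,mnar_steepness Logistic missingness parameters;
#'   `mnar_steepness = 0` disables missingness entirely.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_proteins = 2000,
                       class_fractions = c(chromatin_binder = 0.20,
                                           nucleoplasmic = 0.20,
                                           cytoplasmic = 0.40,
                                           background = 0.20),
                       baseline_log2_mean = 25,
                       baseline_log2_sd = 2,
                       fraction_effects = default_fraction_effects(),
                       n_conditions = 3,
                       conditions = NULL,
                       n_replicates = 3,
                       fraction_of_changing_proteins = 0.10,
                       condition_effect_sd = 1,
                       condition_effect_size = NULL,
                       fraction_of_affinity_proteins = 0.10,
                       affinity_effect_sd = 0,
                       affinity_effect_size = NULL,
                       chromatin_enrichment = c(chromatin_binder = 2,
                                                nucleoplasmic = -0.5,
                                                cytoplasmic = -2,
                                                background = 0),
                       noise_sd = 0.3,
                       mnar_midpoint = 21,
                       mnar_steepness = 1,
                       seed = 1) {
  cls <- c("chromatin_binder", "nucleoplasmic", "cytoplasmic", "background")
  if (!setequal(names(class_fractions), cls))
    stop_("class_fractions must be named over: %s", paste(cls, collapse = ", "))
  class_fractions <- class_fractions[cls]
  if (abs(sum(class_fractions) - 1) > 1e-8)
    stop_("class_fractions must sum to 1 (got %.4f)", sum(class_fractions))
  if (any(class_fractions < 0)) stop_("class proportions must be >= 0")
  if (n_replicates < 2) stop_("n_replicates must be >= 2")
  for (s in c(baseline_log2_sd, condition_effect_sd, affinity_effect_sd,
              noise_sd))
    if (s < 0) stop_("standard deviations must be >= 0")
  if (is.null(conditions))
    conditions <- c("naive", "formative", "primed", "hESC")[seq_len(n_conditions)]
  if (length(conditions) != n_conditions)
    stop_("length(conditions) must equal n_conditions")
  structure(list(
    n_proteins = as.integer(n_proteins),
    class_fractions = class_fractions,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    fraction_effects = fraction_effects,
    n_conditions = as.integer(n_conditions),
    conditions = conditions,
    n_replicates = as.integer(n_replicates),
    fraction_of_changing_proteins = fraction_of_changing_proteins,
    condition_effect_sd = condition_effect_sd,
    condition_effect_size = condition_effect_size,
    fraction_of_affinity_proteins = fraction_of_affinity_proteins,
    affinity_effect_sd = affinity_effect_sd,
    affinity_effect_size = affinity_effect_size,
    chromatin_enrichment = chromatin_enrichment,
    noise_sd = noise_sd,
    mnar_midpoint = mnar_midpoint,
    mnar_steepness = mnar_steepness,
    seed = seed
  ), class = "sim_params")
}

# deterministic class assignment: counts proportional to class_fractions
assign_classes <- function(params) {
  n <- params$n_proteins
  counts <- floor(params$class_fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- params$class_fractions * n - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  rep(names(params$class_fractions), counts)
}

mnar_mask <- function(true_log2, params) {
  # steepness 0 is the documented "no missingness" switch (the logistic
  # would otherwise degenerate to a constant 1/2)
  if (params$mnar_steepness == 0)
    return(rep(FALSE, length(true_log2)))
  p <- stats::plogis(-params$mnar_steepness * (true_log2 - params$mnar_midpoint))
  stats::runif(length(true_log2)) < p
}

protein_labels <- function(n) sprintf("P%05d", seq_len(n))

#' Simulate a six-fraction chromatin-purification experiment
#'
#' Generates log2 intensities for all six gradient fractions in one
#' condition with `n_replicates` replicates each. Chromatin binders carry
#' positive mean enrichment in the chromatin washes and depletion from the
#' cytoplasm; the cytoplasmic class the reverse. Missingness follows the
#' logistic MNAR model on the true (pre-noise) log2 intensity.
#'
#' @param params A [sim_params()] object.
#' @return A list with `matrix` (an [intensity_matrix()]), `design` (a
#'   [sample_design()]) and `truth` (a `ground_truth` list with per-protein
#'   class and true fraction-enrichment vectors).
#' @export
simulate_fraction_experiment <- function(params = sim_params()) {
  with_seed(params$seed, {
    n <- params$n_proteins
    cls <- assign_classes(params)
    base <- stats::rnorm(n, params$baseline_log2_mean, params$baseline_log2_sd)
    fr <- GRADIENT_FRACTIONS
    eff <- params$fraction_effects[cls, fr, drop = FALSE]
    cond <- params$conditions[1]
    fvec <- rep(fr, each = params$n_replicates)
    rvec <- rep(seq_len(params$n_replicates), times = length(fr))
    cols <- paste(fvec, rvec, sep = "_")
    design <- sample_design(cols, fvec, cond, rvec)
    true <- matrix(base, n, length(cols)) + eff[, fvec, drop = FALSE]
    obs <- true + matrix(stats::rnorm(n * length(cols), 0, params$noise_sd),
                         n, length(cols))
    obs[mnar_mask(true, params)] <- NA_real_
    dimnames(obs) <- list(protein_labels(n), cols)
    truth <- structure(list(
      protein_id = protein_labels(n),
      class = cls,
      baseline_log2 = base,
      fraction_effects = eff
    ), class = "ground_truth")
    list(matrix = intensity_matrix(obs, scale = "log2"),
         design = design, truth = truth)
  })
}

#' Simulate matched chromatome and proteome phase experiments
#'
#' Generates two matched log2 intensity matrices (chromatome layer and total
#' proteome) over `n_conditions` conditions with `n_replicates` replicates
#' per layer. A declared subset of proteins carries condition effects shared
#' by both layers; a disjoint subset carries chromatome-only "affinity"
#' effects with the proteome truth held constant, so the true affinity effect
#' equals chromatome truth minus proteome truth by construction.
#'
#' @param params A [sim_params()]; `n_conditions >= 1` (between-condition
#'   tests require >= 2).
#' @return List with `chromatome`, `proteome` (both [intensity_matrix()]),
#'   `design` (covering both layers; chromatome columns carry fraction
#'   `"chromatome"`, proteome columns `"proteome"`) and `truth`.
#' @export
simulate_phase_experiment <- function(params = sim_params()) {
  if (params$n_conditions < 1) stop_("n_conditions must be >= 1")
  with_seed(params$seed, {
    n <- params$n_proteins
    nc <- params$n_conditions
    nr <- params$n_replicates
    conds <- params$conditions
    cls <- assign_classes(params)
    base <- stats::rnorm(n, params$baseline_log2_mean, params$baseline_log2_sd)

    enr <- params$chromatin_enrichment
    enr <- if (length(enr) == n && is.null(names(enr))) as.numeric(enr)
           else if (!is.null(names(enr))) unname(enr[cls])
           else stop_("chromatin_enrichment must be per-class named or length n_proteins")

    draw_effects <- function(frac, sd, size) {
      idx <- logical(n)
      eff <- matrix(0, n, nc, dimnames = list(NULL, conds))
      n_sel <- round(frac * n)
      if (n_sel > 0 && nc >= 2) {
        sel <- sample.int(n, n_sel)
        idx[sel] <- TRUE
        for (j in 2:nc) {
          eff[sel, j] <- if (!is.null(size))
            size * sample(c(-1, 1), n_sel, replace = TRUE)
          else stats::rnorm(n_sel, 0, sd)
        }
      }
      list(idx = idx, eff = eff)
    }
    ch <- draw_effects(params$fraction_of_changing_proteins,
                       params$condition_effect_sd,
                       params$condition_effect_size)
    # affinity subset disjoint from the changing subset
    af <- {
      idx <- logical(n)
      eff <- matrix(0, n, nc, dimnames = list(NULL, conds))
      n_sel <- round(params$fraction_of_affinity_proteins * n)
      pool <- which(!ch$idx)
      if (n_sel > 0 && nc >= 2 && length(pool)) {
        sel <- pool[sample.int(length(pool), min(n_sel, length(pool)))]
        idx[sel] <- TRUE
        for (j in 2:nc) {
          eff[sel, j] <- if (!is.null(params$affinity_effect_size))
            params$affinity_effect_size * sample(c(-1, 1), length(sel), replace = TRUE)
          else stats::rnorm(length(sel), 0, params$affinity_effect_sd)
        }
      }
      list(idx = idx, eff = eff)
    }

    make_layer <- function(true_cond, fraction) {
      cols <- as.vector(vapply(conds, function(cc)
        paste(fraction, cc, seq_len(nr), sep = "_"), character(nr)))
      cvec <- rep(conds, each = nr)
      true <- true_cond[, rep(seq_len(nc), each = nr), drop = FALSE]
      obs <- true + matrix(stats::rnorm(n * length(cols), 0, params$noise_sd),
                           n, length(cols))
      obs[mnar_mask(true, params)] <- NA_real_
      dimnames(obs) <- list(protein_labels(n), cols)
      list(mat = intensity_matrix(obs, scale = "log2"),
           design = sample_design(cols, fraction, cvec,
                                  rep(seq_len(nr), nc)))
    }
    prot_true <- matrix(base, n, nc) + ch$eff
    chrom_true <- prot_true + enr + af$eff
    proteome <- make_layer(prot_true, "proteome")
    chromatome <- make_layer(chrom_true, "chromatome")
    design <- sample_design(
      c(chromatome$design$sample_id, proteome$design$sample_id),
      c(chromatome$design$fraction, proteome$design$fraction),
      c(chromatome$design$condition, proteome$design$condition),
      c(chromatome$design$replicate, proteome$design$replicate)
    )
    truth <- structure(list(
      protein_id = protein_labels(n),
      class = cls,
      baseline_log2 = base,
      chromatin_enrichment = enr,
      is_changing = ch$idx,
      is_affinity = af$idx,
      condition_effects_proteome = ch$eff,
      condition_effects_chromatome = ch$eff + af$eff,
      affinity_effects = af$eff
    ), class = "ground_truth")
    list(chromatome = chromatome$mat, proteome = proteome$mat,
         design = design, truth = truth)
  })
}

#' Simulate a ChIP-MS pulldown versus IgG experiment
#'
#' Generates log2 iBAQ-style intensities for a bait complex plus background
#' proteins in specific-antibody pulldown and IgG control triplicates.
#' Complex members' expected iBAQ equals bait iBAQ times their stoichiometry
#' (before noise); background proteins have equal expected intensity in
#' pulldown and IgG; in the IgG control, complex members sit
#' `igg_log2_depletion` log2 units lower and are mostly lost to MNAR
#' missingness.
#'
#' @param stoichiometries Named numeric vector of molar ratios relative to
#'   the bait; must contain the bait at 1.0.
#' @param bait Name of the bait protein (must be in `stoichiometries`).
#' @param n_background Number of background proteins.
#' @param conditions Condition labels (one pulldown+IgG triplicate set each).
#' @param n_replicates Replicates per group.
#' @param bait_log2_ibaq True log2 iBAQ of the bait in the pulldown.
#' @param background_log2_mean,background_log2_sd Background abundance
#'   hyperparameters (log2).
#' @param igg_log2_depletion Log2 units by which complex members are depleted
#'   in the IgG control.
#' @param noise_sd Replicate noise SD (log2).
#' @param mnar_midpoint,mnar_steepness Logistic MNAR parameters.
#' @param seed Integer seed.
#' @return List with `matrix`, `design`, `truth` (classes, stoichiometries).
#' @export
simulate_chipms <- function(stoichiometries, bait,
                            n_background = 500,
                            conditions = "naive",
                            n_replicates = 3,
                            bait_log2_ibaq = 30,
                            background_log2_mean = 24,
                            background_log2_sd = 2,
                            igg_log2_depletion = 6,
                            noise_sd = 0.2,
                            mnar_midpoint = 21,
                            mnar_steepness = 1,
                            seed = 1) {
  if (!bait %in% names(stoichiometries))
    stop_("bait '%s' absent from the stoichiometry map", bait)
  if (abs(stoichiometries[[bait]] - 1) > 1e-12)
    stop_("the bait must have stoichiometry 1.0")
  if (any(stoichiometries <= 0)) stop_("stoichiometries must be positive")
  with_seed(seed, {
    members <- names(stoichiometries)
    bg_ids <- sprintf("BG%04d", seq_len(n_background))
    ids <- c(members, bg_ids)
    n <- length(ids)
    nr <- n_replicates
    bg_base <- stats::rnorm(n_background, background_log2_mean,
                            background_log2_sd)
    true_pd <- c(bait_log2_ibaq + log2(unname(stoichiometries)), bg_base)
    true_igg <- c(bait_log2_ibaq + log2(unname(stoichiometries)) -
                    igg_log2_depletion, bg_base)
    cols <- c(); fvec <- c(); cvec <- c(); rvec <- c()
    for (cc in conditions) for (f in c("pulldown", "igg"))
      for (r in seq_len(nr)) {
        cols <- c(cols, paste(f, cc, r, sep = "_"))
        fvec <- c(fvec, f); cvec <- c(cvec, cc); rvec <- c(rvec, r)
      }
    true <- matrix(0, n, length(cols), dimnames = list(ids, cols))
    true[, fvec == "pulldown"] <- true_pd
    true[, fvec == "igg"] <- true_igg
    obs <- true + matrix(stats::rnorm(n * length(cols), 0, noise_sd),
                         n, length(cols))
    prm <- list(mnar_midpoint = mnar_midpoint, mnar_steepness = mnar_steepness)
    obs[mnar_mask(true, prm)] <- NA_real_
    design <- sample_design(cols, fvec, cvec, rvec)
    truth <- structure(list(
      protein_id = ids,
      class = c(rep("complex", length(members)), rep("background", n_background)),
      bait = bait,
      stoichiometries = stoichiometries,
      true_log2_pulldown = true_pd,
      true_log2_igg = true_igg
    ), class = "ground_truth")
    list(matrix = intensity_matrix(obs, scale = "log2"),
         design = design, truth = truth)
  })
}

#' Serialize ground truth as JSON
#'
#' Ground truth is written next to the simulated matrices for recovery
#' testing; analysis code never reads it.
#'
#' @param truth A `ground_truth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  x <- lapply(unclass(truth), function(el) {
    if (is.matrix(el)) as.data.frame(el) else el
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
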