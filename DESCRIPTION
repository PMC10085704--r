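Package: chromatome
Title: Quantitative Analysis of Chromatin-Associated Proteomes
Version: 0.1.0
Authors@R:
    person("Chromatome", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream statistical analysis of chromatin-enrichment
    proteomics (chromatome) experiments starting from wide protein-group
    intensity matrices. Provides Gaussian-downshift imputation of
    left-censored missing values, s0-moderated two-sample tests and
    multi-sample ANOVA with permutation-based false discovery rates,
    paired proteome-normalized chromatome tests, fraction-profile
    classification of high-confidence chromatin binders by k-means
    clustering of z-scored profiles, relative chromatin binding
    statistics, Fisher's exact annotation enrichment with
    Benjamini-Hochberg correction, ChIP-MS differential enrichment
    versus IgG controls and bait-normalized complex stoichiometry, and a
    seeded synthetic-data generator with full ground truth for pipeline
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
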