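Package: metgain
Title: Genetic Gain Analysis for International Multi-Environment Wheat Yield Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate grain-yield genetic gains from multi-year,
    multi-site wheat yield trial networks in which the entry set turns over
    every year and each cooperating site contributes a local check variety.
    Provides a synthetic trial-network generator with known ground truth
    (alpha-lattice layouts, a built-in annual genetic trend, factor-analytic
    site-wise genetic covariance, and two climate groups), per-site
    alpha-lattice mixed-model fitting with heritability-based site
    filtering, k-means climate classification of sites into high- and
    low-rainfall environments, a multi-site linear mixed model with a
    factor-analytic genotype-by-environment covariance fitted by REML to
    produce BLUPs for every line in every environment, genetic-gain
    regressions per se and relative to local checks for the five
    highest-yielding lines, and physiological-trait trend and sequential
    partial R-squared contribution analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
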