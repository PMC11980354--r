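Package: paleohaz
Title: Parametric Hazard Models for Skeletal Age-at-Death Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for paleodemographic mortality analysis of skeletal
    assemblages. Fits Gompertz and Gompertz-Makeham hazard models to
    individual age-at-death estimates by maximum likelihood, with a
    proportional-hazards covariate (e.g., sex), Wald and profile-likelihood
    confidence intervals, and likelihood-ratio model comparison. Includes
    transition-analysis-style Bayesian age estimation from ordinal skeletal
    trait stages, sectioning-point metric sex classification with a
    morphological reconciliation rule, and a seeded synthetic cemetery
    assemblage generator for power studies and pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
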