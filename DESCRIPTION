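Package: hostsdm
Title: Two-Stage Host-Specialist Ensemble Species Distribution Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A config-driven pipeline for two-stage ensemble species
    distribution modelling of a host plant and its specialist herbivores.
    Implements occurrence cleaning and spatial thinning, derivation of the 19
    bioclimatic predictors from monthly climate grids, pseudo-absence
    sampling, repeated stratified cross-validation, TSS/AUC model gating with
    TSS-weighted ensemble combination, jackknife variable importance with
    collinearity pruning, maximum sensitivity-specificity binarization, and
    range-dynamics statistics (range expansion ratio, index of range
    similarity, host-specialist range overlap). Ships a virtual-species
    synthetic-data generator with known truth so the whole cascade is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
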