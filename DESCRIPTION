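Package: ftdnet
Title: Explainable Differential Diagnosis of Frontotemporal Dementia
    Subtypes from Parcellated Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential diagnosis of the three frontotemporal dementia
    subtypes (bvFTD, nfvPPA, svPPA) from parcellated structural-MRI
    morphometric features: 360 cortical-patch thickness values, 360
    cortical-patch volumes and 15 subcortical volumes per subject.
    Implements GLM-based w-score harmonization with a designated reference
    diagnostic group, a two-level multi-type parallel feature-embedding
    neural classifier trained with class-weighted cross-entropy, stratified
    nested cross-validation with probabilistic ensembling and balanced-
    accuracy evaluation, Integrated-Gradient feature attribution, and
    patch-wise group-contrast linear models with Benjamini-Hochberg FDR
    control. Ships a multi-site synthetic-cohort simulator with planted
    subtype atrophy and batch effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
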