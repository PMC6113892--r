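Package: gpdm
Title: General Polytomous Diagnosis Modeling for Cognitive Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the general polytomous diagnosis model (GPDM), a saturated
    cognitive-diagnosis model for polytomous item responses that combines the
    G-DINA modeling process with graded-response item splitting. Provides
    EM-based marginal maximum likelihood estimation with optional monotonicity
    constraints, linear design-matrix transformations to saturated and reduced
    (PDINA/PDINO) parameterizations with delta-method standard errors,
    simulation- and residual-based model-fit assessment using Fisher-transformed
    item-pair correlations, attribute classification, and a fully seeded
    simulation harness for classification-accuracy and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
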