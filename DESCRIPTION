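Package: collidersim
Title: Collider Bias from Selective Participation in Cohort Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo machinery for studying how selection into (or
    attrition from) a large cohort study distorts association estimates
    through collider conditioning. Simulates an intended study population
    in which a polygenic allele score predicts a phenotype, imposes
    logistic selection driven by phenotype and outcome, fits the
    unadjusted outcome-on-allele-score regression in the selected sample,
    and aggregates replicate grids of bias, z-scores and
    confidence-interval coverage. Includes an inverse-probability-weighted
    estimator that removes the induced bias when the selection model is
    known, and a small linear-Gaussian graph simulator for qualitative
    selection-bias scenarios, including the classic two-coins-and-a-bell
    collider toy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    pracma,
    purrr,
    Rcpp,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
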