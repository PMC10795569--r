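Package: ersirt
Title: Extreme Response Style Corrections in Multigroup Item Response Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how the choice of an item response model for
    extreme response style (ERS) affects conclusions about latent group
    differences on Likert-type questionnaires.  Implements probability
    kernels, simulators and multigroup marginal-maximum-likelihood
    estimators for three models of four-category responses: a
    multidimensional nominal response model with a prespecified scoring
    matrix, a three-node item response tree (IRTree) with multidimensional
    nodes, and a generalized partial credit model control that ignores
    response style.  Includes a simulation pipeline that crosses data
    generating model, number of items, threshold asymmetry and group ERS
    mean shift, and summarises bias in the focal group's substantive trait
    mean and variance, together with fit indices, EAP person scoring and
    probability-curve reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
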