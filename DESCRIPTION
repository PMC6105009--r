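Package: relsal
Title: Relevance Learning and Aberrant Salience Modelling for Cued Outcome-Detection Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of implicit relevance
    learning in probabilistic cued outcome-detection experiments. Provides a
    task generator for a two-feature (color and shape) design with reversing
    80/20 contingencies, a two-branch binary hierarchical Gaussian filter
    whose first-level precision formalises subjective relevance, reaction-time
    response models built on relevance-weighted unsigned prediction errors and
    irrelevance-weighted manifestation biases, maximum-a-posteriori fitting
    with Laplace-approximate model evidence, random-effects Bayesian model
    selection with protected exceedance probabilities and family inference,
    raw reaction-time analyses including a ground-truth aberrant-salience
    score, and parameter/model-recovery validation tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    withr,
    generics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
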