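Package: cogirt
Title: Item Response Theory Based Pharmacometric Modeling of Cognitive
    Assessment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Combined item response theory (IRT) and pharmacometric framework
    for item-level cognitive assessment data such as the ADAS-cog. Provides
    mixed-format item models (three-parameter logistic, binomial word tests,
    a four-parameter word-recognition extension, truncated generalized
    Poisson counts, proportional-odds rater items), marginal maximum
    likelihood estimation of item parameters with a standard-normal latent
    cognitive disability, Fisher-information based ranking of assessment
    components in specified patient populations, a linear latent disease
    progression model with correlated random effects, a fractional drug
    effect and interval-censored dropout, clinical trial simulation, and
    power / type-I-error comparison of the longitudinal IRT analysis against
    least-squares means and total-score mixed-model analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
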