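Package: geoburden
Title: Subnational Disease-Burden Estimation with Model-Based Geostatistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based geostatistical estimation of childhood diarrhoeal
    disease burden at subnational scale. Simulates survey worlds with a known
    space-time prevalence truth, filters covariates by variance inflation,
    builds stacked-generalisation ensemble covariates, fits a Bayesian
    binomial space-time Gaussian-process model producing joint posterior
    draws of prevalence, converts draws to incidence and mortality, rakes
    them to national envelopes, aggregates to administrative units with
    uncertainty intervals and Gini-based inequality metrics, and runs
    counterfactual risk-factor attribution of averted deaths.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    ranger,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
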