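Package: ormeta
Title: Random-Effects Meta-Analysis of Odds Ratios from 2x2 Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits seven random-effects models that estimate a summary odds
    ratio from a series of 2-by-2 tables: the conventional two-stage
    normal-normal model (DerSimonian-Laird, maximum likelihood and REML
    heterogeneity estimators, with Q-profile confidence intervals for the
    between-study variance), five binomial logistic generalised linear mixed
    models fitted by maximum likelihood with adaptive Gauss-Hermite
    quadrature (fixed or random study intercepts, two random-slope codings,
    and an unstructured bivariate model), and the hypergeometric-normal
    conditional model together with its rare-event binomial and Peto
    approximations.  Includes a simulation engine for evaluating bias,
    precision and confidence-interval coverage of all models under
    configurable generative settings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    lme4,
    optparse
Config/testthat/edition: 3
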