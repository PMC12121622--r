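Package: polypcount
Title: Zero-Inflated and Hurdle Models for Colorectal Polyp Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Regression models for zero-heavy polyp counts from colonoscopy
    screening studies: logistic, Poisson, robust Poisson, negative binomial
    and generalized Poisson regression, zero-inflated (ZIP, ZIRP, ZINB,
    ZIGP) and zero-hurdle (ZHP, ZHNB) maximum-likelihood fits with
    model-based and Huber sandwich variance. Includes the accompanying
    diagnostic battery (score and bias-corrected Vuong tests for excess
    zeros, dispersion tests after excess-zero removal, chi-square goodness
    of fit, information criteria), a flowchart-driven model selector,
    marginal standardization of polyp detection rates, and a Monte Carlo
    engine for evaluating bias, precision and coverage of the competing
    estimators on simulated zero-inflated count data.
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
    MASS,
    sandwich,
    glmmTMB,
    withr,
    jsonlite
Config/testthat/edition: 3
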