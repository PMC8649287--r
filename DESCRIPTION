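Package: bpvar
Title: Usual Blood Pressure Variability and Cardiovascular Risk Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating "usual" (regression-dilution-corrected)
    visit-to-visit systolic blood pressure variability from short longitudinal
    series with a heteroscedastic Bayesian hierarchical model, and for relating
    it to cardiovascular and mortality outcomes through counting-process Cox
    models with attained-age bands, floating absolute risks, geometric-mean
    decade hazard ratios, restricted cubic splines, exact Poisson incidence
    intervals, and multiple imputation with Rubin's-rule pooling. Includes a
    calibrated synthetic cohort generator with known ground truth for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    MASS,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
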