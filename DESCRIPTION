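Package: questenm
Title: Time-Specific Presence-Absence Ecological Niche Models for Tick
    Questing Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calibration, selection and temporal projection of logistic
    presence-absence ecological niche models for questing-tick
    surveillance data. Daily gridded climate variables are composited to
    8-day periods, reduced to orthogonal predictors by principal
    components analysis, and matched in space and time to site-visit
    detection records. Niche signal is assessed with multivariate
    PERMANOVA and univariate randomization tests against the sampling
    universe. All combinations of linear and quadratic responses of the
    principal components are fitted as binomial GLMs, screened by a
    four-filter cascade (unimodal responses, cross-validated AUC and
    TSS, delta-AIC), and combined into an Akaike-weight ensemble that is
    transferred to every weekly layer, smoothed, aggregated to
    day-weighted monthly means, and accompanied by mobility-oriented
    parity (MOP) extrapolation diagnostics. A synthetic-data generator
    with a known unimodal niche supports end-to-end testing without
    climate downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
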