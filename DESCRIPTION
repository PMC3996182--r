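Package: ventdss
Title: Two-Stage Decision Support for Mechanical Ventilator Settings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Clinical decision support for mechanical ventilation of
    respiratory patients. Stage one scores candidate diagnoses (COPD, ARDS,
    cerebrovascular disease) with a finding-frequency probability model built
    from per-disease occurrence tables of fifteen physiological findings.
    Stage two recommends four ventilator settings (breath frequency, tidal
    volume, FiO2, pressure- versus volume-support mode) with single-hidden-
    layer perceptrons trained by six algorithms (Levenberg-Marquardt,
    Bayesian regularization, one-step secant, BFGS quasi-Newton, and
    cyclical- or sequential-order incremental weight/bias updates),
    benchmarked by k-fold cross-validation. Includes plausibility screening
    of patient records, a synthetic cohort generator that reproduces the
    reference finding frequencies exactly, and reporting of per-output
    success rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
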