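Package: gcsteroid
Title: Granulosa-Cell Steroidogenesis Modelling and Endocrine-Disruptor
    Prediction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic ordinary-differential-equation model of the last
    steps of ovarian sex-steroid synthesis (androstenedione, testosterone,
    estrone, estradiol) in rat granulosa cells.  Simulates primary-culture
    (two-compartment) and whole-ovary (three-compartment, estrous-cycle
    forced) systems with competitive Michaelis-Menten interconversion,
    FSH-controlled gene expression and endocrine-disruptor fold-change
    perturbations.  Includes hierarchical Bayesian calibration of the
    kinetic parameters from in vitro endpoints by Metropolis-Hastings
    sampling, convergence diagnostics, metabolic flux analysis, and
    Monte-Carlo prediction of ovarian estradiol under endocrine disruption.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
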