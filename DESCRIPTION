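Package: hdprog
Title: Continuous-Time Hidden Markov Disease Progression and Societal Cost
    Modelling for Huntington's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits progressive continuous-time hidden Markov models (CTHMMs)
    to irregularly spaced longitudinal clinical visit data, with support for
    exact and interval-censored death observations, a calibrated upper-bound
    correction for life-expectancy bias under heavy right-censoring,
    cross-validated selection of the number of disease states, and grouped
    principal component feature construction with an iterative re-grouping
    rule that enforces low within-state feature correlation.  A four-category
    UK societal cost model (state benefits, therapies, lost GDP contribution,
    and care) is attached to fitted states, and Monte-Carlo simulation of
    synthetic patient populations supports "what-if" analyses of
    interventions that delay disease-state transitions.  A synthetic cohort
    generator emulating the structure of longitudinal Huntington's disease
    observational data is included for testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
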