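Package: quotasim
Title: Markov Microsimulation of an Anaesthesia Workforce under
    Foreign-Trainee Quotas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time, capacity-constrained Markov microsimulation of the
    anaesthesia workforce of the French- and Italian-speaking cantons of
    Switzerland under a strict quota-and-return policy for foreign trainees.
    Generates an individual-level synthetic cohort matching published survey
    marginals, projects annual training/transition/fixed/retired state censuses
    over a decade with Monte-Carlo uncertainty bands, calibrates the residual
    foreign-departure hazard against published projection endpoints, and
    converts transition-position headcounts into full-time-equivalent coverage
    to quantify the staffing gap in senior-registrar positions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
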