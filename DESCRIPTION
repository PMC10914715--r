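Package: metsbn
Title: Discrete Bayesian Networks for the Dynamic Progression of Metabolic Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Models the bidirectional progression of the metabolic syndrome
    (MetS) in longitudinal cohorts with discrete Bayesian networks. Provides
    Joint Interim Statement component classification and four-state disease
    staging (FMD/MMD/SMD/MetS) with forward/reverse transition accounting;
    score-based hill-climbing structure learning under whitelist/blacklist
    arc constraints with bootstrap model averaging; Dirichlet posterior-mean
    estimation of conditional probability tables; exact inference by variable
    elimination with causal and evidential reasoning reports; a synthetic
    longitudinal cohort generator for end-to-end testing without access to
    the source survey; and JSON/BIF network serialization.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
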