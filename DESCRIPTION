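Package: viamon
Title: Statistical Tools for Seed Genebank Viability Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical machinery for managing the viability of orthodox
    seed collections in genebanks: modified-Jeffreys binomial confidence
    intervals and exact binomial tests for germination results, probit
    survival-curve fitting of seed storage experiments (estimating initial
    viability Ki and the probit rate sigma, with p50/p85 percentile storage
    times), Ellis-Roberts viability-equation predictions from user-supplied
    species constants, tolerance testing of replicated germination counts,
    Wald sequential test plans, a monitoring-schedule planner implementing
    the one-third-of-time-to-threshold interval rules, and a cohort
    simulator with known ground truth for fixtures and policy comparison.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
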