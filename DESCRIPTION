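Package: fawnsurv
Title: Neonatal Ungulate Age Models and Staggered-Entry Known-Fate Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating hoof-growth equations that estimate the age of
    newborn ungulates (white-tailed deer, mule deer, pronghorn) and for
    propagating age-estimation error into staggered-entry known-fate survival
    analysis. Provides a registry of published age-from-hoof-growth equations,
    accuracy scoring against known-age animals, a synthetic cohort simulator
    with age-dependent mortality and collar shedding, construction of daily and
    weekly encounter histories with right-censoring, maximum-likelihood fitting
    of known-fate interval-survival models with group-equality constraints,
    AICc ranking with Akaike weights, and chi-square contrasts of survival
    estimates.
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
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
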