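Package: xylodyn
Title: Intra-Annual Wood Cell Development Kinetics, Phenology and
    Rate-Duration Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intra-annual xylogenesis monitored by
    repeated micro-core sampling. Fits Gompertz cumulative cell-production
    curves to per-tree wood cell counts with a tree-level random effect on
    the asymptote, derives growth-rate kinetics (inflection date, maximal
    and average rates, 5-95% development window), detects cambial phenology
    (onset, end and duration of the enlargement phase) and bimodal
    within-season extrema of phase trajectories, tests age trends, and
    decomposes final cell number into rate and duration contributions via
    LMG relative importance. Includes a synthetic multi-phase trajectory
    generator with per-tree asymptote heterogeneity for validation and
    power studies.
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
    minpack.lm,
    nlme,
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
    knitr
Config/testthat/edition: 3
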