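Package: odofuzz
Title: Fuzzy Expert-System Ranking of Odonate Species from Field Observations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a fuzzy rule-based expert system for identifying
    dragonfly and damselfly (Odonata) species from partial field
    observations. Species/sex classes are ranked by a relevance score that
    multiplies seven coefficients: data-driven commonality, a presence-grid
    position coefficient, a trained biotope preference, trapezoidal fuzzy
    seasonality and altitude memberships, a suborder match, and a colour
    coefficient obtained by composing the observer's colour selection with
    expert colour-similarity, colour-admissibility and colour-exclusion
    relations. Includes loaders and validators for occurrence-record tables
    and expert knowledge bases, model training from occurrence records,
    rank-based accuracy evaluation (mean/median position, top-k
    probability, 95th-percentile rank), and a synthetic-data generator so
    the whole pipeline is testable without any real dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
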