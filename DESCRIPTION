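Package: saltscen
Title: Counterfactual Salt-Reduction Scenarios from Food-Diary Microdata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates how much daily salt intake a surveyed adult population
    could forgo if umami substances (glutamate, inosinate, guanylate) partially
    replaced sodium in selected food categories. Reads individual-level food-diary
    records, converts sodium to salt equivalent, maps food codes to a registry of
    umami-substitutable categories with literature-derived sodium-reduction
    bounds, applies market-share scenarios for low-sodium products, and
    aggregates reductions by gender and age band with the reporting conventions
    of population dietary surveys. Includes a seeded synthetic-cohort generator
    emulating a UK adult food-diary survey so the full pipeline is testable
    without access to restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
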