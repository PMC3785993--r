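Package: frailmap
Title: Frailty Assessment by Weighted Gower Similarity and Treemaps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for similarity-based frailty assessment of
    elderly patients. Implements a canonical 61-variable mixed-type frailty
    schema (anthropometric, functional, nutritional, cognitive, geriatric
    syndromes, and accelerometer-derived gait dispersion measures), the
    weighted Gower general similarity coefficient with missing-value and
    carried-forward ("kept") value handling, similarity-ranked treemap
    construction with depth and branching limits, tri-axial accelerometer
    feature extraction, synthetic cohort generators, and a longitudinal
    nutritional-evolution analysis with per-sex stage means and trend
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
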