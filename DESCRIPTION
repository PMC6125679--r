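Package: radscreen
Title: Radiosensitivity Screen Scoring and Clonogenic Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for high-throughput radiosensitivity
    RNA-interference screens and their follow-up assays. Implements
    clonogenic survival analysis (plating efficiency, surviving fraction,
    constrained linear-quadratic fitting, SER10 sensitization ratios,
    two-way ANOVA curve comparison), screen hit scoring (non-targeting
    control normalization, R-scores from the mean absolute deviation of
    control wells, rank products across replicate runs with permutation
    p-values, Z-factor assay quality, top-N hit selection), cytogenetic
    summaries (chromosome aberrations per metaphase and per 100 cells,
    sister chromatid exchange rates, relative reporter repair efficiency),
    and rule-based classification of time-lapse lineage fates. Ships a
    synthetic-data generator with known ground truth so every stage of the
    pipeline can be exercised and validated without laboratory data.
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
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
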