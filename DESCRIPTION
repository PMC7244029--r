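Package: degage
Title: Integrative Differential Expression Analysis for Physiological Aging
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for calling differentially expressed genes between groups of
    animals split by physiological age rather than chronological age. Implements
    quantile normalization, present/absent probe calling from a per-sample
    two-component Gaussian mixture, an integrative two-group test combining a
    pooled-variance Student t statistic and a log2 median ratio through
    permutation-derived empirical null distributions (Gaussian kernel density
    estimation) and Stouffer's method, a permutation-calibrated maximum
    fold-change procedure for aging time-series expression with k-means and
    hierarchical classification of trajectories into up/down/others, and
    concordance tables between directional gene sets. Includes synthetic-data
    generators with known ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
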