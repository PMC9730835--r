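Package: soilscore
Title: Config-Driven Soil Health Scoring with Distance-to-Target Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Hierarchical soil-health assessment for agricultural fields.
    Converts measured topsoil and field properties into unitless 0-1 soil
    function indicators through configurable evaluation curves keyed by
    soil type and land use, aggregates them in three weighted steps
    (limiting-factor weighting within categories, recency weighting across
    years, indicator-count weighting across categories) into category
    sub-scores and a final score, substitutes visual soil assessment
    ratings for model-derived physical indicators where available,
    recommends the most effective farming practice per category, and
    audits itself via redundancy (Spearman correlation, PCA), single
    property error propagation and aggregation-method comparison. Includes
    a reproducible generator of multi-year synthetic field records,
    including good/poor field pairs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    optparse,
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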