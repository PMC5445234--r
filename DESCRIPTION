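Package: recall24
Title: Multi-Pass 24-Hour Dietary Recall Capture and Method-Validation Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for web-style self-administered 24-hour dietary
    recall studies. Provides a structured food and supplement database with
    portion-size image anchors, probe questions, linked foods and search tags;
    a multiple-pass recall session state machine that resolves reported
    portions to gram weights; per-day and mean-daily nutrient and food-group
    intake computation with energy adjustment; and the complete two-method
    agreement analysis used to validate dietary assessment instruments:
    Pearson/Spearman correlations with deattenuation for within-person
    day-to-day variance, quartile cross-classification, Bland-Altman limits of
    agreement, normality-routed difference tests, and recovery/concentration
    biomarker correlations with 24-hour urine completeness screening. A
    synthetic-data module simulates cohorts with realistic between- and
    within-person intake variance so the whole pipeline is testable without
    study data.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
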