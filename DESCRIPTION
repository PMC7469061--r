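Package: meddietr
Title: Mediterranean Diet Adherence Scoring and Island-Mainland Cohort Comparison
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing adherence to the Mediterranean diet from
    food-frequency-questionnaire (FFQ) data and for comparing two
    geographically defined sub-populations of a birth cohort. Implements
    conversion of raw day/week/month consumption frequencies to daily
    frequencies, uninformative-variable filtering, cumulative food-group
    frequencies, an adapted 23-point Mediterranean Diet Serving Score
    (MDSS, with the original 24-point variant), the 9-component
    Mediterranean Diet Score for pregnant women (MDS-preg),
    Mann-Whitney U comparisons across all variables with Bonferroni
    correction, PCA loadings of scaled food-group frequencies, and a
    repeated 75/25 train/test random-forest island-vs-mainland
    classification harness with imbalanced-classification metrics and
    importance-based variable selection. A configurable synthetic
    two-population cohort generator makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
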