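Package: equisym
Title: Vertical Movement Asymmetry Analysis for Riding Horses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies vertical movement asymmetry of the head and pelvis in
    trotting horses from displacement signals or stride-level parameter tables.
    Provides a waveform simulator with known ground truth, stride segmentation
    and extrema-difference parameters (HDmin, HDmax, PDmin, PDmax), iterative
    Mahalanobis outlier removal and trial inclusion rules, threshold-based
    symmetric/asymmetric classification with a stride-variability condition,
    Total Asymmetry Scores for straight-line and lunge trials, prevalence,
    double-threshold, concordance and upper-quartile summaries, and
    mixed-effects association models between rider-perceived sidedness
    questionnaire responses and asymmetry magnitudes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    ggplot2,
    readr,
    lme4,
    lmerTest,
    emmeans,
    e1071,
    MASS,
    generics
Suggests:
    testthat (>= 3.0.0),
    broom,
    jsonlite,
    withr
Config/testthat/edition: 3
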