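Package: hpsleep
Title: Hypomanic Personality and Sleep: Cohort Simulation and Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline linking a dimensional bipolar-vulnerability
    trait (hypomanic personality) to objective actigraphy and subjective
    (Pittsburgh Sleep Quality Index) sleep measures in older adults.
    Provides a seeded synthetic cohort generator with a three-factor probit
    item model and configurable cross-domain effects on both the level and
    the night-to-night variability of sleep parameters; per-subject
    actigraphy summaries (means and intraindividual standard deviations);
    questionnaire scoring for the 44-item hypomanic personality scale and
    the PSQI; tetrachoric factor analysis with parallel-analysis retention,
    promax rotation and Thurstone regression scores; covariate-adjusted
    partial Spearman correlation grids with multiple-test correction,
    dependent-correlation contrasts and decile extreme-group tests; a
    block-structure-preserving permutation null with quantile-quantile
    envelopes; and ten-fold cross-validated incremental prediction.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    mvtnorm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
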