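Package: raschval
Title: Partial Credit Model Calibration and Psychometric Validation of
    Multi-Object Risk-Perception Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and validating polytomous rating scales
    administered repeatedly across several assessment objects (products or
    behaviours) and two risk framings. Implements partial credit model
    calibration by marginal maximum likelihood, weighted likelihood (WLE)
    and maximum likelihood person measurement, Rasch measurement theory
    diagnostics (fit residuals, class-interval chi-squares, threshold
    ordering, targeting, local dependence, person separation index),
    differential item functioning by two-way ANOVA of standardized
    residuals, an auditable iterative item-reduction loop, classical test
    theory scale evaluation, raw-score-to-measure conversion tables with a
    0-100 scaled metric, construct-validity comparisons (known-group
    t-tests, Spearman correlations with disattenuation, carry-over
    assessment), and a synthetic survey generator emulating a stratified
    multi-product risk-perception panel study.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    car,
    e1071,
    pracma,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
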