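Package: tonguecomplexity
Title: Tongue Shape Complexity Metrics and Mixed-Model Analysis for
    Ultrasound Tongue Contours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the two standard midsagittal tongue-shape complexity
    statistics from ultrasound tongue-spline coordinates: the number of
    inflections (NINFL), a trimmed count of curvature sign changes, and the
    modified curvature index (MCI), the integral of unsigned curvature along
    the contour. Applies the conventional token-exclusion rules (NINFL over 5,
    MCI over 6), and fits the associated cohort-level models: cumulative-link
    (ordinal) mixed models for NINFL and linear mixed models for MCI, with
    treatment-coded diagnosis or accuracy predictors, deviation-coded phoneme
    contrasts, centred age, and by-speaker random effects. Includes a
    synthetic-data module that generates tongue-like contours with known
    ground-truth complexity and cohort datasets from the generative
    mixed-model structure, so that the whole pipeline can be exercised and
    verified without external data.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
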