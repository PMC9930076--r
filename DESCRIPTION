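Package: ulpkin
Title: Kinematic and Patient-Reported Outcome Comparison for Upper-Limb
    Prosthesis Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for cross-over studies comparing multi-grip
    (MHP) and standard (SHP) myoelectric hand prostheses. Provides trial
    segmentation by velocity threshold, gimbal-lock artifact screening,
    cubic-spline time-normalization to 500 steps, range of motion, kinematic
    variability, kinematic repeatability (adjusted coefficient of multiple
    determination), and shoulder coordination-pattern classification for
    7-joint angle recordings; an SPSS-convention statistics battery
    (normality-routed t tests and Mann-Whitney, Levene-routed pooled/Welch t,
    chi-squared with Cramer's V, two-way fully-within repeated-measures ANOVA
    with Mauchly's test, Greenhouse-Geisser correction and generalized eta
    squared, and effect-size conversions with magnitude labels); scoring for
    the OPUS-UEFS, TAPES-upper, RAND-36, EQ-5D-5L, D-QUEST and PUF-ULP
    instruments with pluggable weight tables; and a synthetic-data generator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
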