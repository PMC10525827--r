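Package: embryokin
Title: Kinematic Analysis of Stimulus-Evoked Movement in Chicken Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing pipeline for markerless pose-estimation output
    from in-ovo recordings of chicken embryos. Reads the three-header-row
    pose-track CSV dialect, applies likelihood-based and robust-distance
    quality control, computes per-frame kinematic parameters (beak gap,
    beak angle, landmark displacement), aggregates them into 30-second
    interval sums with median imputation of tracking dropouts and a
    missingness-based exclusion rule, and contrasts post-stimulus windows
    against baseline with linear mixed models (random embryo intercept,
    Tukey-adjusted marginal-mean contrasts) and paired sign-flip
    permutation tests. Includes an ethogram module for beak-movement
    event tallies and responder percentages, and a synthetic cohort
    generator with ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    emmeans,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
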