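Package: navkin
Title: Movement Kinematics and Factorial Inference for Multisensory VR
    Navigation Trials
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for within-subject virtual-reality obstacle
    avoidance experiments with haptic and audio feedback. Provides a seeded
    synthetic-cohort generator (2-D goal-directed walker with condition
    dependent obstacle detection, hesitation, and head motion), telemetry
    readers and writers, quadratic (Savitzky-Golay) smoothing of position and
    Euler-angle series, per-trial movement metrics (completion time, collision
    count, trajectory length, spectral arc length smoothness, Shannon entropy
    of head pitch and of head-body yaw difference), per-cell IQR outlier
    screening, two-way repeated-measures mixed-model ANOVA and the
    Scheirer-Ray-Hare rank test, questionnaire descriptives, and an
    end-to-end reproducible pipeline with interaction-plot data export.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    dplyr,
    ggplot2,
    lme4,
    lmerTest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
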