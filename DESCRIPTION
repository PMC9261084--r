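Package: soameta
Title: Sense-of-Agency Psychophysics: Signal Detection, Metacognition and
    Clinical Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for embodied sense-of-agency (SoA) experiments
    comparing psychosis patients and healthy controls on a virtual-hand
    sensorimotor conflict-detection task. Provides a validated trial-level
    data model with pre-registered exclusion handling, a calibrated synthetic
    cohort generator built on an equal-variance signal-detection observer,
    per-participant sensitivity and bias (d-prime, criterion), type-2
    metacognition via Goodman-Kruskal gamma rank correlations between
    confidence and accuracy, a leave-p-out nearest-centroid classifier on
    per-aspect psychometric slopes with permutation null and
    Kolmogorov-Smirnov testing, BIC-compared mixed-effects model ladders for
    agency judgments and confidence, and Pearson correlations with clinical
    scales (PANSS, SPQ-B).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
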