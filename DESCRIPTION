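Package: trailgaze
Title: Eye-Tracking Trail-Making Test Scoring, Mixed Models and Dominance
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for a computerized, eye-tracking version of
    the Trail-Making Test (TMT) with a within-subject speed/accuracy task-set
    manipulation. Converts raw gaze samples to degrees of visual angle,
    detects saccades, fixations and blinks with velocity/acceleration
    thresholds, classifies fixations as guiding or searching against target
    areas of interest, and computes eight trial-level test scores (trial
    duration, fixation duration, saccade amplitude, fixation counts,
    eye-hand span, scanpath length). Fits random-intercept linear mixed
    models by profiled (RE)ML from scratch, computes Zellner-Siow (JZS)
    Bayes factors by deterministic quadrature, and implements a dominance
    analysis that classifies each test score as driven by the experimental
    manipulation or by interindividual variability, with Nakagawa marginal
    and conditional R-squared and cluster-bootstrap confidence intervals.
    A synthetic-data module generates layouts, event-level trials and
    score-level datasets with the statistical structure the analysis
    assumes, so the full pipeline is testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    lme4,
    lmerTest,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
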