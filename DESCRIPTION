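Package: gazecluster
Title: Cluster-Based Permutation Analysis of Anticipatory Gaze in the Visual-World Paradigm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing visual-world eye-tracking experiments on
    anticipatory (predictive) eye movements: reading fixation reports,
    assigning areas of interest, expanding fixations to 1-ms samples and
    aggregating them into 100-ms bins time-locked to a critical word,
    empirical log-ratio (logit) gaze-preference scores, within-subject
    adjusted confidence intervals, two-stage cluster-based randomization
    inference with condition-swap and zero-reference permutation null
    schemes, Likert scale scoring with Cronbach's alpha, and cluster-level
    regression of gaze preference on explicit attitude scores. Includes a
    synthetic-data generator emulating a 2 x 3 repeated-measures Latin-square
    design with condition-specific anticipatory gaze dynamics, so the whole
    pipeline runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
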