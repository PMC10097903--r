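Package: dualspeed
Title: Dual-Task Street-Crossing Simulation and Processing-Speed Score Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates immersive dual-task sessions in which a walker crosses a
    two-lane virtual street while answering audio-visual Stroop match/mismatch
    stimuli, extracts the 68 behavioral and Stroop-performance features used in
    digital processing-speed assessment (crossing counts and times, time to
    collision, trajectory dispersion and entropy, velocity statistics, head-turn
    counts, attention-matrix dispersion, Stroop accuracy and response time),
    screens features against a 0-19 clinical processing-speed score by Pearson
    correlation, and estimates the score with LASSO, support vector and gradient
    boosted regression under leave-one-subject-out cross-validation with
    per-fold recursive feature elimination, including Bland-Altman agreement and
    feature-set comparison utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    e1071,
    xgboost,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
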