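Package: saccmask
Title: Saccadic Choice Masking Analysis with Accuracy-Matched Surrogate Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing saccadic choice experiments in which target
    visibility is degraded by object-substitution masking, backward masking or
    contrast reduction. Provides minimum saccadic reaction time estimation via
    a consecutive-bin chi-square criterion, cumulative accuracy time-courses
    with bootstrap confidence bands, and an accuracy-matched resampling
    surrogate null for testing whether the fastest saccades escape masking.
    Includes a QUEST Bayesian adaptive staircase engine, robust outlier
    screening of reaction times (medcouple-adjusted boxplot fences), saccade
    detection from gaze traces, and a synthetic observer/experiment simulator
    for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
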