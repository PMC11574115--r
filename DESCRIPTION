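Package: patkit
Title: Analysis Toolkit for the Phase Adjustment Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing cardiac interoceptive accuracy data from the
    Phase Adjustment Task (PAT): parsing of nested session records, trial-level
    quality control and engagement metrics, circular consistency scoring of
    selected tone delays, two-component Gaussian-mixture classification of
    participants as interoceptive or non-interoceptive via Bayes-factor
    thresholds, time-domain heart rate variability from baseline beat series,
    and laboratory-versus-remote group comparisons. Includes a session
    simulator with known ground truth so every stage of the pipeline can be
    exercised and validated without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    dplyr,
    purrr,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
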