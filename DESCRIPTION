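Package: fearext
Title: Simulation and Analysis of Fear Conditioning and Extinction Psychophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing differential fear
    conditioning/extinction experiments with electrodermal and rating
    outcomes. Generates pseudo-randomized trial sequences with
    counterbalanced cue assignment, synthesises skin-conductance recordings
    from a bi-exponential response kernel with an intolerance-of-uncertainty
    (IU) moderated amplitude model, scores trial-locked skin conductance
    responses by trough-to-peak analysis with threshold, window and artifact
    rules, square-root transforms and reduces amplitudes to condition-by-time
    magnitude cells, classifies learners from conditioned-response scores,
    and fits the 2x2 repeated-measures ANCOVA with a continuous mean-centered
    moderator, simple-slopes contrasts at +/- 1 SD, partial eta squared, and
    hierarchical regressions with delta R squared.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
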