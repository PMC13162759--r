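Package: narousal
Title: Continuous Arousal Dynamics from Annotations, Pupillometry and EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for continuous emotional arousal during
    naturalistic viewing: pupil-trace cleaning with luminance regression,
    inter-subject correlation with circular time-shift surrogate nulls,
    aperiodic (1/f) plus Gaussian-peak spectral parametrization with
    individual-alpha-frequency detection, time-resolved band-power
    correlation with group arousal trajectories, and cluster-mass
    sign-flip permutation statistics. Includes a synthetic-cohort
    generator with known arousal-power couplings so every stage is
    testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
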