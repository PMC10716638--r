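Package: gazediv
Title: Divergence Point Analysis for Visual-World Eye-Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bootstrap divergence point analysis of visual-world
    eye-tracking experiments. Fixation events are coded binomially into 50 ms
    time bins locked to a spoken-word onset, mapped onto analysis roles
    (targets vs distractors, participant- vs speaker-compatible objects in a
    gender-stereotype design), and summarised as fixation-proportion curves.
    The divergence point -- the first of at least ten consecutive 50 ms bins
    in which a one-sample t-test against 0.50 is significant -- is estimated
    with a non-parametric bootstrap that resamples whole trials within
    participant-by-image-type strata and reports a percentile confidence
    interval. A seeded synthetic-data generator reproduces the counterbalanced
    2x2 stereotype design and simulates gaze as a Markov chain with known true
    divergence time, so every pipeline stage can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
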