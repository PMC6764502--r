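Package: emowm
Title: Scoring and Group Analysis for Continuous-Report Emotional
    Working-Memory Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delayed-estimation (continuous-report) working-memory
    and perceptual-matching tasks in which facial expressions are reproduced
    on a bipolar valence scale (fearful = -100..-1, neutral = 0,
    happy = +1..+100). Provides trial-level scoring (absolute error, signed
    emotional bias, per-emotion bias with sign-flip normalization, binned
    psychometric curves), valence-categorization analysis (proportion correct
    by intensity bin and its slope), trial-exclusion filters, balanced trial
    schedule generators, a generative response simulator for end-to-end
    pipeline checks and parameter recovery, and group-level inference:
    Welch/paired/one-sample t tests with Cohen's d, mixed repeated-measures
    ANCOVA with Greenhouse-Geisser correction, and effect-size confidence
    intervals via noncentral distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
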