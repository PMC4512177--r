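Package: eyeblinkr
Title: Delay Eyeblink Conditioning Analysis with Probability-Amplitude
    Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for delay eyeblink conditioning in head-fixed
    mice. Separates the probability of producing a learned eyelid response
    from the amplitude of the responses that occur, by reflecting the
    negative side of the per-session peak-amplitude histogram across zero to
    estimate the failure rate. Includes a protocol-faithful trial scheduler
    and generative eyelid-trace simulator with ground-truth labels, trace
    normalization against the unconditioned reflex blink, conditioned- and
    unconditioned-response detection and timing (onset latency, 10-90% rise
    time, peak latency), photic eyelid-opening detection, and the
    repeated-measures statistics used to compare genotype cohorts
    (t-tests, one-way ANOVA with Bonferroni planned comparisons, two-way
    mixed-design ANOVA, ANCOVA with age and Tukey HSD, Cohen's d).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    multcomp,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
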