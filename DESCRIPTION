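Package: liftforce
Title: Simulation and Validation of Handle- and Platform-Based Lifting
    Force Measures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how precision-grip lifting forces are
    measured in weight-perception experiments.  Simulates dual-transducer
    lifting trials (a handle recording half the applied force and a
    platform that can only record force reduction up to lift-off),
    builds transition-balanced pseudo-random trial sequences, extracts
    the standard dependent measures (peak load and grip forces and rates,
    force at first rate peak, load phase durations, normalised heaviness
    ratings), and computes the validity statistics used to compare the
    two recording methods: ICC(3,1) with exact-F confidence intervals
    and 2x2 repeated-measures ANOVA with Bonferroni-corrected switch
    contrasts and Cohen's d.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
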