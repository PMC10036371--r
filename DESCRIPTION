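Package: mmntrack
Title: Tracking Auditory Mismatch Negativity and P3a Across Repeated
    Oddball Recording Blocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and statistical detection of auditory mismatch
    negativity (MMN) and P3a event-related potentials across repeated
    recording blocks of a multi-deviant oddball paradigm.  Provides a
    synthetic oddball EEG generator with block-level presence control
    ("waxing and waning"), ERP preprocessing (zero-phase band-pass
    filtering, baseline correction, peak-to-peak artifact rejection,
    per-condition averaging), serial permutation t-tests with Tmax
    family-wise correction for paired and independent designs,
    BIC-approximation Bayes-factor timecourses with Lee-Wagenmakers
    evidence categories, windowed peak and effect-size extraction, a
    per-block presence/absence detection ledger, detection-rate tables,
    and a deviant-by-block repeated-measures ANOVA with
    Greenhouse-Geisser correction for group habituation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    arrow,
    car,
    dplyr,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
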