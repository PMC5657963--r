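Package: notchsurv
Title: Audiometric Notch Detection and Design-Based Survey Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects high-frequency audiometric notches indicative of
    noise-induced hearing loss in pure-tone audiograms, and estimates their
    population prevalence and association with noise exposure from complex
    survey data. Provides the notch classification rule (any 3, 4 or 6 kHz
    threshold at least 15 dB HL above the 0.5/1 kHz average, with at least
    5 dB recovery at 8 kHz), design-based prevalence estimation with
    Taylor-linearized standard errors, survey-weighted logistic regression
    with clustered sandwich variances, a synthetic audiogram cohort
    generator with known ground truth, readers for SAS XPORT health-survey
    files, and an end-to-end pipeline producing prevalence and odds-ratio
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    foreign,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
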