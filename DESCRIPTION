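Package: kinedecode
Title: Decoding Gender, Personality and Music Preference from Dance Motion Capture
Version: 0.1.0
Authors@R:
    person("Kine", "Decode Maintainers", email = "maintainers@kinedecode.org",
           role = c("aut", "cre"))
Description: Tools for decoding individual differences from full-body
    motion-capture recordings of free dance. Implements correntropy-based
    joint-covariance movement features, preprocessing of optical marker data
    (joint derivation, root-centred local coordinates, Butterworth and
    Savitzky-Golay velocity estimation), cross-validated linear decoding
    (linear support vector machine for gender, Bayesian linear regression and
    principal-component regression for Big-Five personality traits and genre
    preferences), joint-importance attribution from model weights, and
    comparison of importance profiles by Spearman correlation, Ward
    clustering and classical multidimensional scaling. Ships a seeded
    synthetic-cohort simulator so the full pipeline is testable without
    access to motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
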