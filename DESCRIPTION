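Package: groupfa
Title: Group Factor Analysis with a Shared Diagonal Error Covariance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a group (mixture) factor analysis model in which each
    subject group carries its own factor loading matrix and mean vector
    while all groups share a single diagonal covariance of measurement
    errors. Estimation is by an expectation-maximisation algorithm with
    group memberships either fixed to clinical diagnoses (supervised) or
    recomputed as posterior responsibilities (soft). Includes varimax
    rotation, sign and permutation alignment of loadings across groups via
    the Hungarian algorithm, factor-retention and factor-score normality
    diagnostics, per-feature analysis of variance, and a seeded generator
    of synthetic cohorts drawn from the generative model. Designed for
    continuous morphometry feature tables such as intracranial-volume
    normalized subcortical volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
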