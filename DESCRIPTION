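Package: promisref
Title: Reference Values and IRT Scoring for the PROMIS Global Health Scale
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for working with the 10-item PROMIS Global Health
    instrument: graded-response-model scoring (response-pattern EAP
    estimation and Lord-Wingersky summed-score conversion tables) of the
    mental-health and physical-health subscales and their 2-item short
    forms, construction of population reference tables by age band and
    gender, anchor-based derivation of interpretability thresholds on the
    T-score metric, representativeness checks of sample margins against
    census margins, and simulation of synthetic survey populations with
    correlated mental and physical latent traits.  Ships the published
    Dutch general-population summary tables (2016) as plain-text data for
    comparison and regression checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
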