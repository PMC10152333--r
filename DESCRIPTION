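Package: judgmentlang
Title: Detection and Disparity Analysis of Judgment Language in Home Health Care Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for studying judgment language (terms such
    as "claims", "insists", "adamant" by which a documenting clinician distances
    themself from a patient's statements) in home health care clinical notes.
    Provides a seeded synthetic note-corpus generator with ground-truth labels,
    corpus-trained word embeddings for lexicon expansion from a seed judgment
    vocabulary, a rule-based matcher with provider-attribution and negation
    exclusions, and disparity statistics: per-race contingency tables with
    relative changes, chi-square tests, fixed and clinician-random-intercept
    logistic regressions (adaptive Gauss-Hermite quadrature) with likelihood
    comparison, and a visit-time linear model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    stringi,
    tibble,
    dplyr,
    rlang,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    knitr,
    rmarkdown
Config/testthat/edition: 3
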