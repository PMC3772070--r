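Package: smoketext
Title: Rule-Based Smoking-Status Extraction from Clinical Free Text with
    Cohort Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies tobacco-smoking mentions (current, past,
    never) in clinical free-text documents using a precision-first,
    sentence-scoped rule engine with negation, temporality and non-tobacco
    exclusion handling. Merges text-derived annotations with structured
    smoking-status fields, resolves one status per patient by the
    first-record-after-referral rule, builds referral cohorts, and computes
    the associated epidemiology: coverage tables, Pearson heterogeneity and
    Cochran-Armitage trend tests, Woolf odds ratios, and grouped-binomial
    logistic regression. Ships a seeded synthetic case-register generator
    with gold annotations so the whole pipeline is testable without patient
    data, plus an annotation-level precision/recall evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
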