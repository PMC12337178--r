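Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance pipeline for spontaneous adverse
    event report databases distributed in the FAERS quarterly ASCII dialect:
    reading the "$"-delimited DEMO/DRUG/REAC/OUTC/RPSR/THER/INDI tables,
    case-level deduplication and deleted-case removal, fuzzy drug-name
    matching for primary-suspect cohort selection, mapping reported reaction
    terms onto a MedDRA-style PT/SOC hierarchy, and four disproportionality
    statistics with their conventional signal criteria: the reporting odds
    ratio (ROR), the proportional reporting ratio (PRR) with Yates-corrected
    chi-squared, the Bayesian confidence propagation information component
    (IC), and the multi-item gamma Poisson shrinker (MGPS) empirical Bayes
    geometric mean (EBGM). Includes descriptive cohort profiling with
    explicit missing-data denominators, time-to-onset analysis from partial
    dates, and a seeded synthetic FAERS-dialect data generator with planted
    drug-event dependencies for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
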