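Package: faersdispro
Title: Disproportionality Analysis of FAERS Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pharmacovigilance signal-detection pipeline for FDA Adverse
    Event Reporting System (FAERS) quarterly ASCII extracts: parsing of
    DEMO/DRUG/REAC tables, FDA-style case deduplication, age harmonization,
    MedDRA preferred-term event queries, drug-event 2x2 contingency tables
    against the full-database background, crude and covariate-adjusted
    reporting odds ratios (logistic regression on collapsed count cells),
    signal criteria with Holm multiple-testing correction, cross-stratum
    Z comparisons, period-split and drug-role sensitivity analyses, and a
    synthetic FAERS-like report generator with known ground-truth reporting
    odds for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
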