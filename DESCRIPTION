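Package: faerstools
Title: Signal Detection and Bias Diagnostics for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("FAERS", "Tools Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reverse-translation analysis of FDA Adverse Event
    Reporting System (FAERS) style spontaneous-report data: parsing of
    quarterly ASCII extracts, normalization of verbatim drug names to
    molecular ingredients by token Tanimoto matching, standardization of
    adverse-reaction verbatims to MedDRA preferred terms by Levenshtein
    similarity, exact-duplicate detection, disproportionality signal
    detection (relative reporting ratio, Yates-corrected chi-square,
    Holm-adjusted q-values, gamma-Poisson empirical-Bayes shrinkage),
    month-resolved signal series with trajectory clustering, and
    quantification of reporting biases (indication-ADR conflation,
    reporter-occupation drift, stimulated reporting).  Ships a seeded
    synthetic report generator with planted ground truth so the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
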