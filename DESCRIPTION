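Package: dystosignal
Title: Disproportionality and Interaction Signal Detection for Drug-Induced
    Dystonia in Spontaneous Reporting Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance pipeline for screening
    drug-induced dystonia in FAERS-style spontaneous reporting data:
    quarterly ASCII ingestion with tolerant date parsing, case/version
    deduplication and deletion-list handling, MedDRA preferred-term case
    definition, four-algorithm disproportionality analysis (ROR, PRR,
    BCPNN information component, MGPS empirical Bayes geometric mean)
    with a conservative combined signal rule, time-to-onset summaries
    with Kaplan-Meier, log-rank and Kruskal-Wallis comparisons, Omega
    shrinkage screening of drug-drug interaction triplets, descriptive
    reporting, and a reporter-occupation (lawyer) exclusion sensitivity
    analysis. Ships a synthetic FAERS-style report generator with a
    ground-truth ledger so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
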