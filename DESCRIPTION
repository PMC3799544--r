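Package: promiscuitr
Title: Compound Promiscuity Statistics from Bioactivity Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies compound promiscuity (specific multi-target activity,
    the molecular basis of polypharmacology) from flat compound-target
    activity tables. Provides high-confidence filtering of Ki/IC50 activity
    records, replicate aggregation on the pPotency scale, per-compound target
    counting, promiscuity-rate and probability-of-promiscuity summaries,
    target-family and molecular-weight stratification, classification of
    promiscuous compounds against the prevalent promiscuity profile, and a
    seeded synthetic-data generator emulating ChEMBL-, DrugBank- and
    PubChem-style extracts so every stage is testable without database
    downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
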