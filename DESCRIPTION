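Package: registerforge
Title: Rule-Based Case Finding, Register Extraction and Audit Validation
    for Electronic Medical Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing research registers from tabular
    electronic medical record (EMR) snapshots with a two-step process:
    rule-based case finding over structured data (ICD diagnosis codes, ATC
    prescription codes, laboratory threshold rules, with configurable
    handling of soft-deleted entries), followed by extraction of the
    included patients' data into a nine-table register. Includes a seeded
    synthetic EMR generator emulating a primary-care record store, and the
    validation protocol used to audit such extractions: stratified random
    patient sampling across calendar periods, an item-level congruity audit
    against the source records, diagnostic accuracy metrics against a
    reference extraction, Venn partition of overlapping inclusion criteria,
    and prevalence estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
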