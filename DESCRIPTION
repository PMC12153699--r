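Package: faersignal
Title: Signal Detection for FAERS Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on FDA Adverse
    Event Reporting System (FAERS) quarterly ASCII extracts:
    dollar-delimited quarterly file ingestion, two-step report
    deduplication, suspect-role exposure cohort construction, narrow-SMQ
    adverse event tagging, descriptive and time-to-onset summaries, and
    case/non-case reporting odds ratio disproportionality with
    signal-of-disproportionate-reporting, IME/DME and label-expectedness
    annotation.  Ships a synthetic FAERS generator with a ground-truth
    ledger so every pipeline stage can be validated end to end without
    external downloads, built around a cardiovascular-safety analysis of
    BRAF and MEK inhibitors in melanoma.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
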