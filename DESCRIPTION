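Package: pvscreen
Title: Disproportionality Screening for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for pharmacovigilance signal detection on FAERS-style
    quarterly extracts of spontaneous safety reports. Reads the standard
    dollar-delimited ASCII tables (DEMO, DRUG, REAC, INDI, OUTC, THER), applies
    the FDA-recommended case deduplication, restricts to an indication-defined
    cohort with primary-suspect drug exposure mapped through a drug dictionary,
    and screens drug-event pairs with the reporting odds ratio (ROR) and the
    shrinkage information component (IC) at both MedDRA preferred-term and
    SMQ level. Covariate-adjusted reporting odds ratios are estimated by
    logistic regression, and time-to-onset and descriptive summaries are
    provided. A deterministic synthetic-report generator with injected
    drug-event reporting rates supports end-to-end validation without access
    to the real database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
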