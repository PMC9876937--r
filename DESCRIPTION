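Package: rmrflow
Title: Resting Metabolic Rate Extraction and Mixed-Model Inference for
    Open-Flow Respirometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for open-flow respirometry of nest-box
    housed small mammals. Converts raw oxygen-fraction traces into
    drift-corrected, STP-corrected oxygen-consumption series, extracts
    hourly resting metabolic rate (RMR) records with low-quantile
    filtering and civil-twilight diel classification, and fits linear
    mixed models relating mass-specific RMR to nest temperature and
    habitat of origin, with AICc-based multimodel selection, Akaike
    weights, evidence ratios and effect sizes (Cohen's f2, ICC,
    marginal/conditional R2). Includes a forward simulator of raw
    respirometry traces, environment logs and metadata with a
    ground-truth ledger for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
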