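Package: bnpcea
Title: Cost-Effectiveness of BNP-Guided Care in Heart Failure with a
    Five-State Markov Cohort Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a monthly-cycle, five-state Markov cohort model of
    rehospitalisation and death in outpatients with heart failure with reduced
    ejection fraction, and uses it to compare B-type natriuretic peptide
    (BNP)-guided care against standard clinical assessment. Provides
    incremental cost-effectiveness analytics (ICER with dominance
    classification, net monetary benefit), deterministic (tornado) and
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves, method-of-moments Beta/Gamma/log-normal parameter distributions,
    non-parametric bootstrap confidence intervals, and a synthetic
    patient-level cohort generator (EQ-5D-3L responses scored with a
    replaceable value set, bottom-up itemised costs) that stands in for a
    400-patient outpatient dataset.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
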