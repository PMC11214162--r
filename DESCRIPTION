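Package: gaguard
Title: Simulation-Based Evaluation of a Gestational-Age Quality-Control Guardrail
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate second- and third-trimester obstetric
    ultrasound cohorts with realistic fetal-biometry and gestational-age
    (GA) error structure, inject novice-level measurement error, and
    evaluate a discrepancy-based guardrail that flags gross GA estimation
    errors. Includes coefficient-table-driven GA dating formulas
    (Intergrowth-21st, Hadlock) with numeric inversion, a moment-matched
    error-model calibrator, ROC cut-point calibration at target
    sensitivities, exact Clopper-Pearson intervals, DeLong AUC inference,
    paired comparison statistics (paired t, McNemar, Wald intervals), and
    an experiment driver for base-case and two-way sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    pROC
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
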