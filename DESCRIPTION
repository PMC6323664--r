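Package: stagecut
Title: Survival Cut-Point Optimization and Staging-System Evaluation for
    Node-Positive Gastric Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finding and validating outcome-based cutoffs in
    metastatic lymph node (MLN) counts for N3 gastric cancer. Implements
    cohort eligibility screening on a patient-level CSV schema, Kaplan-Meier
    estimation and k-group log-rank tests from their defining formulas, a
    maximal log-rank chi-squared cut-point scan over candidate MLN cutoffs,
    Cox proportional-hazards fitting by Newton-Raphson on the partial
    likelihood (Breslow and Efron ties) with a two-step multivariate
    validation of a modified N3a/N3b boundary, TNM (8th edition) stage
    re-grouping under the original and modified N3 definitions, and
    staging-system comparison by likelihood-ratio chi-squared (homogeneity),
    linear-trend chi-squared (discrimination and gradient monotonicity) and
    AIC. A synthetic-cohort generator with a plantable true cutoff supports
    fully reproducible end-to-end analyses without access to registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
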