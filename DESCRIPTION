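Package: ddssfee
Title: Point-Based Reimbursement Modelling for AI Diagnostic Decision Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for valuing AI-based diagnostic decision support services
    within point-based medical fee schedules. Provides a four-dimension
    scoring rubric with canonical point-tier assignment and perturbation
    stability checks, a billing-code registry with point-value regimes and
    the fee formula (points x point value x factor), an illustrative
    diagnostic-accuracy cost-benefit and break-even calculator from the
    payer perspective, crosswalks into RVU-based fee-for-service and
    per-member-per-month capitation systems, and a seedable Monte-Carlo
    cohort simulator that verifies the closed-form expected
    misclassification counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
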