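Package: htnagree
Title: Agreement Analysis for Community Health Worker Hypertension Screening
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical machinery for diagnostic-accuracy studies that
    compare hypertension classification by community health workers (CHWs)
    against physician reference assessment. Implements the rule-based
    blood-pressure measurement protocol and three-way hypertension
    classification engine; clinically weighted Cohen's kappa with
    asymptotic standard errors and one-sided non-inferiority tests against
    minimally acceptable criteria; proportional agreement with Wald
    intervals; binary agreement metrics (kappa, Matthews correlation,
    sensitivity, specificity, predictive values); Bland-Altman
    measurement-agreement analysis; counterfactual attribution of
    discordant classifications to blood-pressure versus history
    differences; simulation-based power analysis for the weighted-kappa
    non-inferiority design; and a synthetic paired-encounter generator so
    the full analysis pipeline is reproducible without access to field
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
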