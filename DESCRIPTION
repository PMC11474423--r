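Package: fevscore
Title: Validation of Clinical Severity Scores for Mortality Prediction in Febrile Adults
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculators for the Modified Early Warning Score (MEWS), the quick
    Sequential Organ Failure Assessment (qSOFA) and the Universal Vital
    Assessment (UVA) score from bedside vital signs, consciousness assessment
    and HIV status, together with the statistical machinery to validate them
    against a binary mortality outcome: tie-corrected Mann-Whitney AUC for
    ordinal scores, DeLong variance and paired AUC-difference tests,
    sensitivity/specificity/PPV/NPV threshold tables, logistic regression
    odds-ratio tables with sparse-score-level grouping, missing-outcome
    sensitivity analyses, and a seeded synthetic febrile-cohort generator
    emulating a four-site multicentre study so the whole pipeline is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
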