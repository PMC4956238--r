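Package: backscreen
Title: Predictive Validity Toolkit for Back-Pain Screening Questionnaires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scoring and diagnostic-validity analysis for two screening
    questionnaires used to identify patients at risk of chronic non-specific
    back pain: the German translation of the Orebro Musculoskeletal Pain
    Screening Questionnaire (OMPSQ, 21 scored items with reverse coding,
    checkbox-missing work items and capped mean substitution) and the
    Heidelberger Kurzfragebogen Rueckenschmerz (HKF-R 10, regression-weighted
    score with five risk categories). Includes dichotomization of 6-month
    follow-up outcomes (pain, function, sick leave), a diagnostic-validity
    engine (ROC coordinate tables, nonparametric AUC with Hanley-McNeil
    standard errors, Youden-optimal cut-offs, likelihood ratios, predictive
    values with Bayesian prevalence re-adjustment, efficiency and quality
    classifications), preliminary between-group ANOVA, a calibrated synthetic
    cohort generator, and an end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
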