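Package: mvsref
Title: Morphokinetic Reference Charts and Variance Scoring for Euploid Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds longitudinal reference charts for the morphokinetic
    milestones of euploid human embryos monitored by time-lapse imaging
    (mean curves via linear mixed-effect regression with natural cubic
    splines, standard-deviation curves via scaled absolute residuals,
    and Gaussian centile grids), scores embryos against a chart with
    per-milestone Z-scores and the morphokinetic variance score (MVS,
    the natural log of the variance of an embryo's Z-scores), and
    evaluates the association of MVS with live birth after single
    euploid frozen embryo transfer (logistic odds ratios, paired ROC/AUC
    comparison, repeated stratified cross-validation for optimism-adjusted
    AUC, NPV-maximizing cutoff selection, and a Cochran-Armitage trend
    test across ICM-by-MVS strata). Includes a calibrated synthetic
    cohort generator so the full pipeline can be exercised and validated
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    pROC,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
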