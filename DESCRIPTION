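Package: brisk
Title: Breast Cancer Risk Prediction from Family History, Mammographic
    Density and Polygenic Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a multiplicative breast cancer risk model that
    combines centered relative risks for family history, mammographic
    density (continuous or categorical), body mass index by menopausal
    status, and a Hardy-Weinberg-normalized polygenic risk score, and
    projects the combined relative risk to absolute 5-year and remaining
    lifetime risk under competing mortality.  Ships the validation
    statistics used to evaluate such models on nested case-control data:
    odds ratio per standard deviation, Mann-Whitney AUC with a DeLong
    test for correlated ROC curves, median-based expected/observed
    calibration with log-scale confidence intervals, clinical risk
    categorization, reclassification tables, and the categorical net
    reclassification improvement with Pencina-Steyerberg standard
    errors.  Includes a seeded case-control cohort simulator and
    packaged published count tables for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
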