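Package: ProteoMACE
Title: Prognostic Biomarker Discovery for Chronic Coronary Syndrome from
    Plasma Proteomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for discovering and
    validating prognostic plasma-protein biomarkers of major adverse
    cardiovascular events (MACE) in chronic coronary syndrome. Implements
    differential-abundance selection (fold change plus Welch's t-test),
    Fisher's exact functional enrichment against a user-supplied annotation,
    incremental feature selection scored by the cross-validated Matthews
    correlation coefficient of a soft-voting classifier (logistic regression,
    support vector machine, random forest), and survival-based validation
    with per-unit Cox hazard ratios, log-rank tests, and a DeLong z-test
    comparing a Framingham-covariate baseline risk model against the model
    augmented with candidate biomarkers. Ships seeded synthetic-cohort
    generators that emulate the discovery and validation study designs so
    every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    glmnet,
    e1071,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
biocViews: Proteomics, BiomedicalInformatics, Classification,
    FeatureExtraction, Survival, DifferentialExpression
RoxygenNote: 7.3.3
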