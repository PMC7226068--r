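Package: radrcc
Title: CT Radiomics and Radiogenomics Risk Modelling for Early-Stage Renal Cell Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for building and validating a CT radiomics risk model of
    post-operative metastasis in organ-confined (pT1) renal cell carcinoma.
    Provides whole/inner/outer tumor region-of-interest partitioning, a
    121-feature radiomics extractor (histogram, gray-level co-occurrence
    matrix, intensity size-zone and morphology families plus semantic
    Hounsfield-unit ratios), ADASYN class balancing, bootstrapped LASSO
    stability selection of a prognostic signature, a Cox proportional-hazards
    radiomics risk score with log-rank optimal cutoff and Kaplan-Meier
    stratification, and radiogenomic linkage of imaging features to gene
    expression through Spearman trait-associated gene sets, Jaccard overlap,
    rank-based enrichment scores and enrichment-subgroup survival. A synthetic
    cohort generator emulating hypodense-core/textured-rim tumors with
    feature-driven survival and planted gene-feature correlations makes the
    whole pipeline testable without protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    glmnet,
    randomForest,
    e1071,
    pROC,
    igraph,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
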