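Package: sepsisPhenoscope
Title: Sepsis Phenotype Discovery and 28-Day Survival Prediction from
    Routine Blood Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotyping intensive-care sepsis admissions from 35
    routine blood-test variables and predicting 28-day survival. Provides a
    synthetic MIMIC-like cohort generator with a four-phenotype mixture
    structure, data conditioning (complete-case exclusion, shifted min-max
    normalization, 7:3 splitting, three-mechanism minority up-sampling),
    K-means phenotype discovery with elbow/silhouette compromise selection of
    the cluster count and 3-D principal-component embedding, self-contained
    nonparametric and survival statistics (Kruskal-Wallis,
    Jonckheere-Terpstra with exact small-sample permutation, Kaplan-Meier,
    Mantel log-rank, Gehan-Breslow-Wilcoxon, and a conservative higher-p
    reporting rule), SOFA and SIC severity scoring from versioned threshold
    tables, a double-coefficient quadratic multivariate fitting function
    (DCQMFF) softmax classifier, a small seven-layer one-dimensional
    convolutional classifier, and ROC/AUC evaluation with standard baseline
    comparators and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    cluster,
    mclust,
    randomForest,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    survival,
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
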