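Package: dcmScreen
Title: Cross-Platform Microarray Integration and Serum Biomarker Panel
    Evaluation for Diabetic Cardiomyopathy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements an in-silico biomarker discovery pipeline for
    diabetic cardiomyopathy: cross-platform microarray integration by
    per-sample quantile discretization, Wilcoxon rank-sum differential
    expression with Bonferroni and Benjamini-Hochberg correction,
    cross-disease intersection of differentially expressed genes and
    top-k candidate ranking. A companion panel-evaluation arm assesses
    longitudinal serum biomarker panels from two-group mouse designs:
    per-week Gaussian GLM group tests, composite scores by principal
    component analysis or logistic regression, ROC analysis with
    Youden-J cutoff selection, and marker correlation against an
    echocardiographic functional readout. Seeded synthetic-data
    generators with known ground truth support end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, tools, S4Vectors, jsonlite
Suggests: testthat (>= 3.0.0), pROC, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'dcmScreen-package.R'
    'diffexp.R'
    'integration.R'
    'io.R'
    'panel.R'
    'pipeline.R'
    'simulate.R'
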