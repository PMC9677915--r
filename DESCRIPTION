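Package: matreotypes
Title: Matrisome Profiling, Matrix Risk Signatures and Prognostic ECM
    Subtypes for Squamous Lung Carcinoma
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling extracellular-matrix (matrisome) gene
    expression in bulk tumor RNA-seq cohorts. Implements the full analysis
    path from raw counts to prognosis: TMM normalization and per-gene
    z-scaling; moderated differential expression of matrisome genes between
    tumor and non-tumor tissue with correlated core-matrisome cluster
    discovery; derivation of a matrix risk signature by elastic-net
    penalized logistic regression with Firth-corrected log-odds weights and
    per-sample risk scoring; discovery of prognostic ECM subtypes
    ("matreotypes") by Monte-Carlo reference-based consensus clustering with
    PAC/RCSI model selection, centroid construction and nearest-centroid
    assignment; canonical squamous subtype classification by Pearson
    nearest-centroid; survival association via Kaplan-Meier, log-rank and
    Cox proportional hazards models; ligand-receptor interaction scoring
    with receptor-class aggregation; single-sample gene-set, fibrosis and
    per-cell module scores; and a negative-binomial synthetic cohort
    generator with planted differential expression, ECM subtypes and
    survival effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    edgeR,
    glmnet,
    survival,
    pROC
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
biocViews: GeneExpression, Transcriptomics, Clustering, Survival,
    Classification, RNASeq
Config/testthat/edition: 3
RoxygenNote: 7.3.3
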