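Package: ProtNet
Title: Temporal Co-Occurrence Networks and Interaction Annotation for
    Marine Protist Amplicon Time Series
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and annotating putative protist-protist
    interactions from monthly amplicon (ASV) time series. Implements
    community temporal analyses (Bray-Curtis lag-similarity profiles,
    Mantel and ANOSIM permutation tests, environmental PC1-distance
    regression), redundancy analysis with adjusted-R2 forward selection
    and Bonferroni-adjusted permutation stopping, seasonal GAM
    detrending and the nonparanormal transform, sparse inverse
    covariance (graphical lasso) estimation with StARS stability
    selection, cross-depth network merging, and taxonomy-aware matching
    of predicted edges against a curated protist interaction database.
    A synthetic-data module generates ASV tables, environmental tables
    and toy interaction databases with known planted dependencies so
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    mgcv,
    vegan,
    igraph,
    randomForest,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, NetworkInference, TimeCourse,
    GraphAndNetwork, Software
RoxygenNote: 7.3.3
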