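Package: grnlayers
Title: Regulator Discovery and Multilayered Gene Regulatory Networks from
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering transcription factors
    (TFs) that regulate a target gene from RNA-seq expression data, and for
    assembling the candidates into a multilayered TF-TF-gene regulatory
    network. Provides FPKM normalization and fold-change/P-value screening of
    differentially expressed genes; a compact weighted co-expression stage
    (soft-threshold selection by scale-free fit, topological overlap,
    average-linkage module detection, module eigengenes and gene
    significance); consensus feature-TF selection combining a Boruta
    shadow-feature procedure over random-forest regression with SVM recursive
    feature elimination; and a bottom-up Gaussian-graphical-model layering
    step that promotes TFs explaining co-expressed gene pairs (high Pearson
    correlation, low partial correlation given the TF) into successive
    regulatory layers. A synthetic-data module generates count matrices with
    planted layered networks and planted differential expression so every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    ranger,
    e1071,
    jsonlite,
    yaml,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
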