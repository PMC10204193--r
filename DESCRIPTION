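Package: g0kit
Title: Quantification of G0 Cell Cycle Arrest from Bulk and Single-Cell
    Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify G0 cell cycle arrest (quiescence) from
    gene expression data. Implements combined Z-score, mean-scaled and
    rank-based signature scoring with tumour-purity adjustment,
    construction and refinement of quiescence gene signatures from
    differential expression tables, classification of samples and single
    cells into stress-response subtypes (bulk rule and kNN reference
    mapping), ensemble elastic-net modelling of genomic dependencies with
    exact linear Shapley attribution, random-forest based reduction of
    the signature for sparse single-cell data, and synthetic data
    generators with known ground truth for validation of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    glmnet,
    ranger,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
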