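Package: scAtlasKit
Title: Hierarchical Cell-Type Annotation and Atlas-Scale Single-Cell Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Toolkit for assembling and annotating large single-cell RNA-seq
    atlases: raw count matrix and curated-metadata input/output, per-cell
    quality control with a simulated-doublet scorer, Wilcoxon marker statistics
    and feature-panel construction, a semi-supervised negative-binomial
    variational latent classifier with two-level hierarchical annotation and
    consensus voting across annotation methods, cross-species ortholog merging
    with latent-space logistic label transfer, proliferative (NPC) gene-module
    scoring, silhouette-based evaluation of covariate mixing in embeddings,
    and covariate-aware pseudobulk negative-binomial GLM differential
    expression with likelihood-ratio tests. Includes a seeded synthetic-atlas
    generator reproducing the statistical structure the pipeline assumes
    (hierarchical cell types with marker genes, per-sample batch effects,
    doublets, mitochondrial fractions, rare proliferative populations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    MASS,
    jsonlite,
    methods,
    nnet,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
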