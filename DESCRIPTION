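Package: fosmap
Title: Whole-Brain Fos Density Mapping and Immediate-Early-Gene Activation
    Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects Fos-positive cells in registered cleared-brain
    light-sheet volumes by a ratio-based 26-neighbourhood local-maximum rule
    with a 1-8 voxel connected-cluster cell definition, converts detections
    to local cell densities (cells per microlitre) with a uniform cubic
    kernel, and compares groups of density maps by voxelwise two-sample
    t-tests with region-level summaries. A companion transcriptomic stage
    scores single-nucleus RNA-seq neuronal clusters for immediate-early-gene
    (IEG) activation: cell quality-control filters, a pluggable per-cluster
    differential-expression stage with Holm-Bonferroni correction, and a
    signed activation score combining panel-gene p-values by Fisher's
    method. Seeded synthetic-data generators for ground-truthed volumes,
    group cohorts and negative-binomial count matrices make every stage
    verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    Matrix,
    RNifti,
    tiff,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
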