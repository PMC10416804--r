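Package: spheroquant
Title: Quantification of 3D Tumor Spheroid Invasion and Single-Cell Count QC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying tumor-cell escape from 3D spheroids imaged
    as confocal fluorescence z-stacks, and for quality control and clustering
    of plate-based single-cell RNA-seq count matrices. Implements
    spacing-aware segmentation of spheroid and escaped-cell surfaces,
    morphometric measurement (volume, marching-tetrahedra surface area,
    Wadell sphericity), spheroid volume estimation from a fitted periphery
    ellipse and imaging depth, spherical-cap surface-area normalization of
    invasion counts, nearest-distance measurement to a smoothed spheroid
    reference surface, phenotype classification of invading cells, and
    per-day invasion time-series metrics. The transcriptomics side provides
    a housekeeping-gene quality filter, a median-of-ratios count
    normalization for clustering, Ward/Euclidean hierarchical clustering,
    and dendrogram-based outlier flagging. A synthetic-data generator with
    analytically known geometry and planted count structure stands in for
    the microscope and sequencer so that every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    EBImage,
    mclust,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
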