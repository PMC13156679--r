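Package: scLipidMSI
Title: Single-Cell Lipidomics from MALDI Mass Spectrometry Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of single-cell lipidomic MALDI mass
    spectrometry imaging (MSI) experiments on adherent cell cultures. Starting
    from per-pixel spectra and co-registered brightfield micrographs, the
    package performs TIC normalization, signal-to-noise peak picking and
    alignment, spatially smoothed k-means detection of cell-containing pixels,
    cell-specific peak filtering, brightfield-guided segmentation of dispersed
    single cells versus cohesive cell groups, construction of single-cell lipid
    feature matrices, parametric empirical-Bayes batch correction across matrix
    application rounds, subsampled SNN/Leiden consensus clustering with
    silhouette-guided selection of the cluster number, and marker-lipid calling
    by fold-change, adjusted p-value and interquartile-range criteria. A
    synthetic-data generator emulating colonies, dispersed cells, class
    structured treatment effects and batch effects provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sva,
    cluster,
    mclust,
    withr,
    yaml,
    optparse
biocViews: MassSpectrometry, ImagingMassSpectrometry, Lipidomics,
    SingleCell, Clustering, BatchEffect, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllGenerics.R'
    'AllClasses.R'
    'simulate.R'
    'preprocess.R'
    'segment.R'
    'quant.R'
    'cluster.R'
    'tsne.R'
    'stats.R'
    'pipeline.R'
    'io.R'
    'scLipidMSI-package.R'
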