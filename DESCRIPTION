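Package: scTrajAlign
Title: Trajectory-Preserving Diagonal Integration of Single-Cell RNA and ATAC Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates unmatched scRNA-seq and scATAC-seq batches into a shared
    trajectory-preserving latent space while simultaneously learning a nonlinear,
    data-specific gene activity function from chromatin regions to genes. The
    latent space is fitted by minimising a diffusion-distance preservation loss
    together with a multi-scale maximum mean discrepancy alignment term, a sparsity
    penalty that constrains the learned region-to-gene map to a genomic-proximity
    prior, and an optional anchor-cell loss. Includes a matched multi-omic
    simulator driven by a two-state transcriptional kinetic model, trajectory
    inference (Leiden clustering plus a minimum spanning tree backbone, diffusion
    pseudotime), spline-based likelihood-ratio testing of features against
    pseudotime, and a suite of integration evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    igraph,
    FNN,
    irlba,
    RSpectra,
    mclust,
    splines,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, Epigenetics, ATACSeq, RNASeq,
    DimensionReduction, BatchEffect, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'data_io.R'
    'de.R'
    'diffusion.R'
    'evaluation.R'
    'networks.R'
    'objectives.R'
    'postprocess.R'
    'scTrajAlign-package.R'
    'simulate.R'
    'training.R'
    'trajectory.R'
    'utils.R'
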