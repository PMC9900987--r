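Package: MuxFISH
Title: Sequential Multiplexed smFISH Analysis from Images to Spatial
    Subpopulation Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for sequential (one gene per round and channel)
    multiplexed single-molecule FISH experiments on tissue sections:
    retrospective flat-field illumination correction, true 3D median
    denoising, integer-voxel inter-round registration, seeded 3D
    watershed cell segmentation, Laplacian-of-Gaussian spot calling with
    an exact 1-D k-means intensity gate separating signal from
    unspecifically bound probes, codebook-based gene decoding, per-cell
    transcript counting into a SingleCellExperiment, grouped z-score
    normalisation, hierarchical subpopulation clustering, strict z > 0
    co-expression gating of named gene modules, and pseudo-colour
    back-mapping of cell groups onto the original section image. A
    synthetic-data generator produces multi-round image stacks and count
    matrices with complete ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml,
    tiff,
    png,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, Spatial, SingleCell, CellSegmentation,
    Visualization
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'MuxFISH-package.R'
    'RcppExports.R'
    'clustermap.R'
    'imageprep.R'
    'io.R'
    'pipeline.R'
    'quantify.R'
    'render.R'
    'segment.R'
    'spots.R'
    'synth.R'
    'utils.R'
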