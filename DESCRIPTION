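Package: scImageHier
Title: Hierarchical Cell-Type Annotation of Single-Cell RNA-Seq via
    Image-Transformed Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates single cells with a two-level (base-type then
    subtype) taxonomy by rendering each cell's gene-expression vector as a
    small image: genes are laid out in two dimensions with t-SNE or UMAP,
    assigned injectively to pixels by linear sum assignment, and the
    resulting images are classified by a compact convolutional network
    trained with an adaptive hierarchical focal loss that re-balances the
    base-level and subtype-level objectives during training. Inference
    masks subtype probabilities outside the predicted lineage, scores
    candidate novel populations by the gap between base-level and
    subtype-level confidence, and attributes decisions back to genes
    through the pixel map using expected-gradients or occlusion
    attributions. Includes a synthetic single-cell data generator with
    planted hierarchical marker structure, readers and writers for dense
    text, MatrixMarket and HDF5 single-cell formats, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    Matrix,
    matrixStats,
    data.table,
    Rtsne,
    uwot,
    clue,
    digest,
    optparse,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    rhdf5
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
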