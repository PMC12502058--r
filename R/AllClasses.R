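#' @import methods
#' @useDynLib scImageHier, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom rnbinom var sd quantile setNames
#' @importFrom utils head tail write.csv read.csv
NULL

#' Two-level cell-type taxonomy
#'
#' Represents the base-type / subtype hierarchy used throughout the package:
#' an ordered set of base types (major lineages, e.g. T cell, B cell), each
#' carrying an ordered, possibly empty, vector of subtypes. A base type with
#' no subtypes is a terminal leaf: its base-level prediction is the final
#' annotation. Exactly two levels are supported.
#'
#' @slot baseNames character vector of unique base-type names, in index order.
#' @slot children named list, one entry per base type (same order as
#'   `baseNames`), each a character vector of subtype names. Subtype names
#'   must be globally unique; order within a vector defines subtype indices.
#'
#' @seealso [readHierarchy()], [encodeLabels()]
#' @export
setClass("CellTypeHierarchy",
  representation(baseNames = "character", children = "list"))

setValidity("CellTypeHierarchy", function(object) {
  msgs <- character()
  bn <- object@baseNames
  ch <- object@children
  if (anyDuplicated(bn))
    msgs <- c(msgs, paste0("duplicate base-type name: ",
      paste(unique(bn[duplicated(bn)]), collapse = ", ")))
  if (length(ch) != length(bn) || !identical(names(ch), bn))
    msgs <- c(msgs, "children must be a named list parallel to baseNames")
  subs <- unlist(ch, use.names = FALSE)
  if (anyDuplicated(subs))
    msgs <- c(msgs, paste0("subtype listed under more than one base type ",
      "(or twice): ", paste(unique(subs[duplicated(subs)]), collapse = ", ")))
  if (any(vapply(ch, function(x) !is.character(x), logical(1))))
    msgs <- c(msgs, "each children entry must be a character vector ",
      "(deeper trees are not supported)")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Fitted gene-to-pixel layout
#'
#' The result of embedding genes in two dimensions and assigning each gene
#' injectively to a pixel of a fixed grid, together with the per-gene min/max
#' normalization statistics estimated on the fitting (reference) cells. A
#' `PixelMap` is everything needed to render any expression vector over the
#' same gene panel as an image comparable with the training images.
#'
#' @slot gridDim integer(2), image height and width in pixels.
#' @slot assignment data.frame with columns `gene`, `row`, `col` (1-based
#'   pixel coordinates, row-major grid); one row per gene, no two genes on
#'   the same pixel.
#' @slot geneMin,geneMax named numeric, per-gene normalization bounds from
#'   the reference cells.
#' @slot coords numeric matrix (genes x 2), the raw 2-D embedding.
#' @slot method `"tsne"` or `"umap"`.
#' @slot perplexity chosen t-SNE perplexity (`NA` for UMAP).
#' @slot seed integer seed the layout was fitted with.
#' @slot nChannels number of identical channels rendered images carry.
#' @export
setClass("PixelMap",
  representation(gridDim = "integer", assignment = "data.frame",
    geneMin = "numeric", geneMax = "numeric", coords = "matrix",
    method = "character", perplexity = "numeric", seed = "integer",
    nChannels = "integer"))

setValidity("PixelMap", function(object) {
  a <- object@assignment
  msgs <- character()
  if (!all(c("gene", "row", "col") %in% names(a)))
    return("assignment needs columns gene, row, col")
  if (anyDuplicated(a$gene))
    msgs <- c(msgs, "duplicate gene in assignment")
  if (anyDuplicated(paste(a$row, a$col)))
    msgs <- c(msgs, "two genes share a pixel (assignment must be injective)")
  if (any(a$row < 1L | a$row > object@gridDim[1L] |
          a$col < 1L | a$col > object@gridDim[2L]))
    msgs <- c(msgs, "assigned pixel outside the grid")
  if (any(object@geneMax < object@geneMin))
    msgs <- c(msgs, "geneMax < geneMin for some gene")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' State of the adaptive hierarchical loss
#'
#' Carries the adaptive weight alpha that balances the base-level and
#' subtype-level focal losses, the momentum beta of its update, the focal
#' focusing parameter gamma, and the most recent per-level losses.
#'
#' @slot alpha adaptive weight in \[0,1\]; the total loss is
#'   `alpha * FL_base + (1 - alpha) * FL_sub`.
#' @slot beta momentum of the alpha update in \[0,1\].
#' @slot gamma focal focusing parameter, >= 0.
#' @slot lastFlBase,lastFlSub focal losses from the most recent step.
#' @slot step number of alpha updates performed so far.
#' @export
setClass("LossState",
  representation(alpha = "numeric", beta = "numeric", gamma = "numeric",
    lastFlBase = "numeric", lastFlSub = "numeric", step = "integer"))

setValidity("LossState", function(object) {
  if (object@alpha < 0 || object@alpha > 1) return("alpha must be in [0,1]")
  if (object@beta < 0 || object@beta > 1) return("beta must be in [0,1]")
  if (object@gamma < 0) return("gamma must be >= 0")
  TRUE
})

#' Synthetic single-cell scenario
#'
#' Parameters of the synthetic scRNA-seq generator: a two-level hierarchy,
#' per-population cell counts, planted lineage-shared and subtype-specific
#' marker blocks with log-scale effect sizes, negative-binomial baseline
#' counts, independent dropout, and optional per-batch log-scale shifts.
#'
#' @slot hierarchy a [CellTypeHierarchy-class].
#' @slot nCellsPerSubtype cells generated per leaf population (each subtype,
#'   and each terminal base type).
#' @slot nGenes total number of genes.
#' @slot lineageBlockSize,subtypeBlockSize marker block sizes.
#' @slot lineageEffect,subtypeEffect marker elevations in log units.
#' @slot dropoutRate independent zeroing probability in \[0,1).
#' @slot dispersion negative-binomial dispersion (variance = mu + disp*mu^2).
#' @slot batchShifts list of per-batch gene-wise log-scale offsets (possibly
#'   empty; cells are then split round-robin across batches).
#' @slot holdoutSubtypes subtypes to exclude from training splits (used by
#'   novel-population experiments).
#' @slot seed integer seed.
#' @export
setClass("SyntheticScenario",
  representation(hierarchy = "CellTypeHierarchy", nCellsPerSubtype = "integer",
    nGenes = "integer", lineageBlockSize = "integer",
    subtypeBlockSize = "integer", lineageEffect = "numeric",
    subtypeEffect = "numeric", dropoutRate = "numeric",
    dispersion = "numeric", batchShifts = "list",
    holdoutSubtypes = "character", seed = "integer"))

setValidity("SyntheticScenario", function(object) {
  h <- object@hierarchy
  nBlocks <- length(h@baseNames) + length(unlist(h@children))
  need <- length(h@baseNames) * object@lineageBlockSize +
    length(unlist(h@children)) * object@subtypeBlockSize
  if (need > object@nGenes)
    return(sprintf("marker blocks need %d genes but nGenes = %d",
      need, object@nGenes))
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    return("dropoutRate must be in [0,1)")
  if (object@lineageEffect <= 0 || object@subtypeEffect <= 0)
    return("effects must be > 0")
  TRUE
})

#' Trained hierarchical classifier
#'
#' A trained checkpoint: the convolutional backbone and the two
#' classification heads (one over base types, one over all subtypes), plus
#' fingerprints of the hierarchy and the pixel map it was trained against.
#' Predictions with a mismatched map or taxonomy are refused.
#'
#' @slot backbone backbone identifier (`"tiny_cnn"`).
#' @slot params named list of weight arrays.
#' @slot cfg named list of architecture/config values (grid size, feature
#'   dimension, class counts, ...).
#' @slot hierarchy the [CellTypeHierarchy-class] trained against.
#' @slot hierFingerprint,mapFingerprint digests used for compatibility checks.
#' @slot lossState final [LossState-class] after training.
#' @slot trainLog per-epoch data.frame (losses, alpha, validation metrics).
#' @slot stepLog per-step data.frame (FL_base, FL_sub, alpha trajectory).
#' @export
setClass("CellTypeModel",
  representation(backbone = "character", params = "list", cfg = "list",
    hierarchy = "CellTypeHierarchy", hierFingerprint = "character",
    mapFingerprint = "character", lossState = "LossState",
    trainLog = "data.frame", stepLog = "data.frame"))
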