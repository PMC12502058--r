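#' Hierarchical classifier configuration
#'
#' @param backbone `"tiny_cnn"` (the self-contained backbone this package
#'   ships) or `"efficientnet_b5"` (accepted for forward compatibility with
#'   large-scale deployments; no implementation is bundled and training with
#'   it raises an informative error).
#' @param featureDim width of the dense feature layer.
#' @param f1,f2 filters in the first/second convolution block (tiny_cnn).
#' @param pool1 pool after the first block as well as the second; `NULL`
#'   (default) decides by grid size — small grids (<= 32) keep full
#'   resolution until after the second block.
#' @return a named list of configuration values.
#' @export
classifierConfig <- function(backbone = c("tiny_cnn", "efficientnet_b5"),
    featureDim = 64L, f1 = 8L, f2 = 16L, pool1 = NULL) {
  backbone <- match.arg(backbone)
  list(backbone = backbone, featureDim = as.integer(featureDim),
    f1 = as.integer(f1), f2 = as.integer(f2), pool1 = pool1)
}

#' Mask subtype probabilities outside the predicted lineage
#'
#' Implements inference-time probability masking: the predicted base type
#' `b* = argmax(baseProbs)` (ties broken toward the lowest index) selects
#' the admissible subtypes; probabilities of subtypes outside `children(b*)`
#' are set to zero and the survivors renormalized to sum to one, yielding a
#' proper conditional distribution over the predicted lineage. If `b*` is a
#' terminal leaf the masked vector is all zeros and the base-type prediction
#' is the final output. Idempotent.
#'
#' @param baseProbs length-nBase probability vector, or cells x nBase matrix.
#' @param subProbs matching subtype probability vector/matrix (raw).
#' @param hier a [CellTypeHierarchy-class].
#' @return masked subtype probabilities, same shape as `subProbs`.
#' @export
maskSubtypeProbs <- function(baseProbs, subProbs, hier) {
  vec <- !is.matrix(baseProbs)
  if (vec) {
    baseProbs <- matrix(baseProbs, 1L)
    subProbs <- matrix(subProbs, 1L)
  }
  out <- matrix(0, nrow(subProbs), ncol(subProbs))
  bstar <- max.col(baseProbs, ties.method = "first")
  childIdx <- lapply(seq_len(nBaseTypes(hier)), function(b)
    subtypeIndicesOf(hier, b))
  for (i in seq_len(nrow(out))) {
    ch <- childIdx[[bstar[i]]]
    if (!length(ch)) next
    p <- subProbs[i, ch]
    s <- sum(p)
    out[i, ch] <- if (s > 0) p / s else rep(1 / length(ch), length(ch))
  }
  if (vec) out[1L, ] else out
}

# forward pass of a trained model on an image stack -> probability matrices
.modelProbs <- function(model, stack) {
  if (model@backbone != "tiny_cnn")
    stop("backbone '", model@backbone, "' has no bundled implementation")
  fw <- .tinyForward(stack, model@params)
  tb <- model@cfg$tempBase %||% 1
  ts <- model@cfg$tempSub %||% 1
  list(base = .softmaxRows(fw$baseLogits / tb),
       sub = .softmaxRows(fw$subLogits / ts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fingerprint of a hierarchy
#'
#' Digest of the taxonomy's structure, stored in checkpoints so a model
#' refuses to run against a different taxonomy.
#' @param hier a [CellTypeHierarchy-class].
#' @export
hierFingerprint <- function(hier) {
  digest::digest(hier@children)
}

#' Save / load a trained model
#'
#' Checkpoints are runtime artifacts serialized with `saveRDS`.
#'
#' @param model a [CellTypeModel-class].
#' @param path file path (`.rds`).
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
readCheckpoint <- function(path) {
  model <- readRDS(path)
  if (!methods::is(model, "CellTypeModel"))
    stop("not a CellTypeModel checkpoint: ", path)
  model
}

# refuse checkpoint/map or checkpoint/hierarchy mismatches
.checkCompatible <- function(model, map = NULL, hier = NULL) {
  if (!is.null(map) && mapFingerprint(map) != model@mapFingerprint)
    stop("pixel map fingerprint does not match the checkpoint; ",
      "the model must be applied with the map it was trained with")
  if (!is.null(hier) && hierFingerprint(hier) != model@hierFingerprint)
    stop("hierarchy fingerprint does not match the checkpoint")
  invisible(TRUE)
}

setMethod("show", "CellTypeModel", function(object) {
  cat("CellTypeModel (", object@backbone, "): ",
    object@cfg$kBase, " base types, ", object@cfg$kSub, " subtypes, ",
    object@cfg$h, "x", object@cfg$w, " images\n", sep = "")
  if (nrow(object@trainLog)) {
    last <- object@trainLog[nrow(object@trainLog), ]
    cat(sprintf("  trained %d epochs; final val loss %.4f, alpha %.3f\n",
      nrow(object@trainLog), last$valLoss, object@lossState@alpha))
  }
})
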