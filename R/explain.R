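#' Per-pixel attribution maps for a class decision
#'
#' Quantifies how much each pixel (hence each gene, via the pixel map)
#' contributed to the model's probability for one class at one level of the
#' hierarchy. Two back-ends:
#'
#' * `"shap"` — expected-gradients SHAP: attributions are
#'   `E[(x - b) * grad S(b + u (x - b))]` over background images `b` drawn
#'   from a reference set and `u ~ U(0,1)`, where `S` is the class softmax
#'   probability. Requires a `background` image stack (typically training
#'   images); seed-controlled sampling.
#' * `"occlusion"` — the dependency-free definitional method: the
#'   attribution of a pixel is `S(original) - S(pixel zeroed)`. Pixels not
#'   assigned to a gene hold 0 already, so their occlusion attribution is
#'   exactly 0.
#'
#' Rendered channels are replicas of one intensity plane, so attributions
#' are computed on (and reported for) that plane — equivalent to summing
#' over channels.
#'
#' @param model a [CellTypeModel-class].
#' @param stack image stack (`n x H x W`) of cells sharing the queried
#'   predicted class.
#' @param level `"base"` or `"subtype"`.
#' @param class class name or 1-based index at that level.
#' @param method `"shap"` or `"occlusion"`.
#' @param map the [PixelMap-class] (needed by `"occlusion"` to enumerate
#'   assigned pixels).
#' @param background image stack of reference cells for `"shap"`.
#' @param nBackground background/interpolation samples per cell (default 50).
#' @param seed seed for background sampling.
#' @return array `n x H x W` of attributions.
#' @export
attributePixels <- function(model, stack, level = c("base", "subtype"),
    class, method = c("shap", "occlusion"), map = NULL, background = NULL,
    nBackground = 50L, seed = 1L) {
  level <- match.arg(level)
  method <- match.arg(method)
  if (dim(stack)[1L] == 0L) stop("empty cell set")
  hier <- model@hierarchy
  classNames <- if (level == "base") baseTypes(hier) else subTypes(hier)
  if (is.character(class)) {
    ci <- match(class, classNames)
    if (is.na(ci)) stop("unknown ", level, " class: ", class,
      " (valid: ", paste(classNames, collapse = ", "), ")")
  } else ci <- as.integer(class)
  if (ci < 1L || ci > length(classNames)) stop("class index out of range")

  if (method == "occlusion") {
    if (is.null(map)) stop("occlusion needs the pixel map")
    .occlusionMaps(model, stack, level, ci, map)
  } else {
    if (is.null(background)) stop("shap needs a background image stack")
    .expectedGradientMaps(model, stack, level, ci, background,
      nBackground, seed)
  }
}

# Class probability used as the attribution score: the *uncalibrated*
# softmax. Temperature calibration rescales confidences monotonically but
# saturates well-classified cells, flattening the per-pixel differences
# occlusion and gradients measure; the raw softmax keeps them resolvable.
.classScore <- function(model, stack, level, ci) {
  fw <- .tinyForward(stack, model@params)
  p <- if (level == "base") .softmaxRows(fw$baseLogits)
    else .softmaxRows(fw$subLogits)
  p[, ci]
}

.occlusionMaps <- function(model, stack, level, ci, map) {
  n <- dim(stack)[1L]; h <- dim(stack)[2L]; w <- dim(stack)[3L]
  idx <- cbind(map@assignment$row, map@assignment$col)
  s0 <- .classScore(model, stack, level, ci)
  out <- array(0, c(n, h, w))
  for (i in seq_len(n)) {
    plane <- stack[i, , ]
    batch <- array(rep(plane, each = nrow(idx)),
      c(nrow(idx), h, w))
    batch[cbind(seq_len(nrow(idx)), idx[, 1L], idx[, 2L])] <- 0
    sv <- .classScore(model, batch, level, ci)
    plane0 <- matrix(0, h, w)
    plane0[idx] <- s0[i] - sv
    out[i, , ] <- plane0
  }
  out
}

# gradient of the class softmax probability w.r.t. input pixels
.scoreInputGrad <- function(model, stack, level, ci) {
  fw <- .tinyForward(stack, model@params)
  pb <- .softmaxRows(fw$baseLogits)     # uncalibrated, as in .classScore
  ps <- .softmaxRows(fw$subLogits)
  n <- dim(stack)[1L]
  if (level == "base") {
    dZb <- pb * (-pb[, ci])
    dZb[, ci] <- dZb[, ci] + pb[, ci]
    dZs <- matrix(0, n, ncol(ps))
  } else {
    dZs <- ps * (-ps[, ci])
    dZs[, ci] <- dZs[, ci] + ps[, ci]
    dZb <- matrix(0, n, ncol(pb))
  }
  .tinyBackward(dZb, dZs, model@params, fw$cache, needInput = TRUE)$dInput
}

.expectedGradientMaps <- function(model, stack, level, ci, background,
    nBackground, seed) {
  n <- dim(stack)[1L]; h <- dim(stack)[2L]; w <- dim(stack)[3L]
  nb <- dim(background)[1L]
  set.seed(seed)
  out <- array(0, c(n, h, w))
  for (i in seq_len(n)) {
    bIdx <- sample.int(nb, nBackground, replace = nBackground > nb)
    u <- runif(nBackground)
    x <- stack[i, , ]
    bgs <- background[bIdx, , , drop = FALSE]
    diffs <- -sweep(bgs, c(2, 3), x, "-")        # x - b, per sample
    interp <- bgs + diffs * array(rep(u, h * w), c(nBackground, h, w))
    grads <- .scoreInputGrad(model, interp, level, ci)
    out[i, , ] <- apply(diffs * grads, c(2, 3), mean)
  }
  out
}

#' Fold pixel attributions back to genes
#'
#' Reads each gene's attribution at its assigned pixel and aggregates over
#' cells: the mean absolute value (importance magnitude) and the mean
#' signed value (direction — negative values mark genes whose *low*
#' expression characterizes the class). Unassigned pixels are ignored.
#'
#' @param maps attribution array `n x H x W` from [attributePixels()].
#' @param map the [PixelMap-class].
#' @param class,level recorded in the output rows.
#' @return data.frame with columns `class`, `level`, `gene`,
#'   `meanAbsAttribution`, `meanSignedAttribution`, `nCells`.
#' @export
foldToGenes <- function(maps, map, class = NA_character_,
    level = NA_character_) {
  if (!identical(dim(maps)[2:3], as.integer(map@gridDim)) &&
      !identical(as.integer(dim(maps)[2:3]), as.integer(map@gridDim)))
    stop("attribution map shape does not match the grid")
  n <- dim(maps)[1L]
  idx <- cbind(map@assignment$row, map@assignment$col)
  vals <- vapply(seq_len(n), function(i) maps[i, , ][idx],
    numeric(nrow(idx)))
  vals <- matrix(vals, nrow(idx), n)
  data.frame(class = class, level = level, gene = map@assignment$gene,
    meanAbsAttribution = rowMeans(abs(vals)),
    meanSignedAttribution = rowMeans(vals),
    nCells = n, stringsAsFactors = FALSE)
}

#' Per-class gene importance for cells of one predicted class
#'
#' Convenience wrapper: renders the cells, keeps those the model assigns to
#' `class` at `level`, computes attribution maps and folds them to genes.
#'
#' @param model a [CellTypeModel-class].
#' @param sce SingleCellExperiment aligned to the model's panel.
#' @param map the [PixelMap-class].
#' @inheritParams attributePixels
#' @param maxCells cap on cells used (attributions average quickly; default
#'   50).
#' @return a gene-importance data.frame as from [foldToGenes()].
#' @export
geneImportance <- function(model, sce, map, class,
    level = c("base", "subtype"), method = c("shap", "occlusion"),
    background = NULL, nBackground = 50L, maxCells = 50L, seed = 1L) {
  level <- match.arg(level)
  method <- match.arg(method)
  stack <- renderImages(sce, map)
  pr <- .modelProbs(model, stack)
  pred <- if (level == "base") {
    baseTypes(model@hierarchy)[max.col(pr$base, "first")]
  } else {
    masked <- maskSubtypeProbs(pr$base, pr$sub, model@hierarchy)
    subTypes(model@hierarchy)[.maskedArgmax(masked)]
  }
  keep <- which(!is.na(pred) & pred == class)
  if (!length(keep))
    stop("no cell is predicted as ", level, " class '", class, "'")
  keep <- head(keep, maxCells)
  maps <- attributePixels(model, stack[keep, , , drop = FALSE], level,
    class, method, map = map, background = background,
    nBackground = nBackground, seed = seed)
  foldToGenes(maps, map, class = class, level = level)
}

#' Top genes for a class
#'
#' @param table gene-importance table ([foldToGenes()] /
#'   [geneImportance()] output, possibly rbind-ed over classes).
#' @param class,level class to rank (must be present in the table).
#' @param k number of genes (capped at the panel size).
#' @return character vector of gene names, by descending mean absolute
#'   attribution; ties broken by name.
#' @export
topGenes <- function(table, class, level, k = 10L) {
  rows <- table[table$class == class & table$level == level, ]
  if (!nrow(rows)) stop("class '", class, "' at level '", level,
    "' not present in the table")
  ord <- order(-rows$meanAbsAttribution, rows$gene, method = "radix")
  head(rows$gene[ord], k)
}
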