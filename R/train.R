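# derive independent substream seeds from one master seed
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + 7919L * k) %% 2147483647L)
}

# stratified train/validation split; stratum = subtype when present, else
# the base type; strata with < 2 members stay entirely in training
.stratifiedSplit <- function(enc, validationFraction, seed) {
  strat <- ifelse(is.na(enc$sub), paste0("base.", enc$base),
    paste0("sub.", enc$sub))
  set.seed(seed)
  val <- integer(0)
  for (s in unique(strat)) {
    idx <- which(strat == s)
    if (length(idx) < 2L) next
    k <- max(1L, round(validationFraction * length(idx)))
    k <- min(k, length(idx) - 1L)
    val <- c(val, sample(idx, k))
  }
  list(train = setdiff(seq_along(strat), val), val = sort(val))
}

#' Train the hierarchical classifier
#'
#' Renders the labeled cells as images, then optimizes the backbone and the
#' two heads jointly with the adaptive hierarchical focal loss: each
#' mini-batch contributes `alpha * FL_base + (1 - alpha) * FL_sub` (the
#' subtype term averaged over cells that carry a subtype label), after which
#' alpha is updated from the momentum-smoothed loss ratio and takes effect
#' on the next step. Fresh random masking is applied to the training images
#' every epoch. A stratified validation split drives early stopping on the
#' total validation loss; the returned checkpoint holds the best-validation
#' weights. Fully deterministic given `seed`.
#'
#' @param sce labeled SingleCellExperiment with a `"lognorm"` assay over the
#'   map's panel, and label columns.
#' @param map the fitted [PixelMap-class].
#' @param hier a [CellTypeHierarchy-class].
#' @param baseLabels,subLabels label vectors; default to colData columns
#'   `baseLabel` / `subLabel`.
#' @param config from [classifierConfig()].
#' @param state initial [LossState-class] (alpha0, beta, gamma).
#' @param epochs maximum epochs (> 0).
#' @param batchSize mini-batch size.
#' @param lr peak Adam learning rate.
#' @param lrSchedule `"cosine"` (default) anneals the learning rate from
#'   `lr` to near zero over `epochs`; `"constant"` keeps it fixed.
#' @param seed master seed; split, masking, shuffling and weight
#'   initialization draw from substreams derived from it.
#' @param maskFraction training-time random-mask fraction.
#' @param weightDecay decoupled weight decay on weight matrices (0 = off).
#' @param featureDropout dropout probability on the dense feature layer
#'   during training (0 = off).
#' @param validationFraction fraction of each stratum held out, in (0,1).
#' @param earlyStopPatience epochs without validation improvement before
#'   stopping.
#' @param adaptiveAlpha set `FALSE` to freeze alpha at its initial value
#'   (fixed-weight ablation).
#' @param verbose print per-epoch progress.
#' @return a [CellTypeModel-class] checkpoint with training logs.
#' @export
trainClassifier <- function(sce, map, hier,
    baseLabels = sce$baseLabel, subLabels = sce$subLabel,
    config = classifierConfig(), state = lossState(),
    epochs = 30L, batchSize = 64L, lr = 1e-3,
    lrSchedule = c("cosine", "constant"), seed = 1L,
    maskFraction = 0.3, weightDecay = 0, featureDropout = 0,
    validationFraction = 0.15,
    earlyStopPatience = 20L, adaptiveAlpha = TRUE, verbose = FALSE) {
  lrSchedule <- match.arg(lrSchedule)
  if (epochs <= 0L) stop("epochs must be > 0")
  if (validationFraction <= 0 || validationFraction >= 1)
    stop("validationFraction must be in (0,1)")
  if (config$backbone != "tiny_cnn")
    stop("backbone '", config$backbone, "' has no bundled implementation; ",
      "use 'tiny_cnn'")
  enc <- encodeLabels(hier, baseLabels, subLabels)
  stack <- renderImages(sce, map)
  h <- map@gridDim[1L]; w <- map@gridDim[2L]
  kBase <- nBaseTypes(hier); kSub <- nSubTypes(hier)

  split <- .stratifiedSplit(enc, validationFraction, .subSeed(seed, 1L))
  presentTrain <- unique(enc$base[split$train])
  if (length(setdiff(seq_len(kBase), presentTrain)))
    warning("base class(es) with zero training support: ",
      paste(baseTypes(hier)[setdiff(seq_len(kBase), presentTrain)],
        collapse = ", "))

  params <- .initTinyCnn(h, w, config$featureDim, kBase, kSub,
    f1 = config$f1, f2 = config$f2, seed = .subSeed(seed, 2L),
    pool1 = config$pool1)
  opt <- .adamInit(params)

  valStack <- stack[split$val, , , drop = FALSE]
  valEnc <- list(base = enc$base[split$val], sub = enc$sub[split$val])
  trIdx <- split$train

  childIdx <- lapply(seq_len(kBase), function(b) subtypeIndicesOf(hier, b))

  stepLog <- list()
  epochLog <- list()
  best <- list(loss = Inf, params = params, epoch = 0L)
  sinceBest <- 0L
  stepN <- 0L

  for (ep in seq_len(epochs)) {
    lrEp <- if (lrSchedule == "cosine")
      lr * (0.05 + 0.95 * 0.5 * (1 + cos(pi * (ep - 1) / epochs)))
      else lr
    masked <- randomMask(stack, map, maskFraction, .subSeed(seed, 100L + ep))
    set.seed(.subSeed(seed, 200L + ep))
    order <- sample(trIdx)          # this stream also drives dropout masks
    batches <- split(order, ceiling(seq_along(order) / batchSize))
    epLoss <- 0
    for (b in batches) {
      xb <- masked[b, , , drop = FALSE]
      encB <- list(base = enc$base[b], sub = enc$sub[b])
      fw <- .tinyForward(xb, params,
        dropProb = if (featureDropout > 0) featureDropout else NULL)
      pb <- .softmaxRows(fw$baseLogits)
      ps <- .softmaxRows(fw$subLogits)
      ls <- hierarchicalLossStep(pb, ps, encB, state)
      alphaUsed <- state@alpha
      if (adaptiveAlpha) state <- ls$state
      dZb <- alphaUsed * .focalGradLogits(pb, encB$base, state@gamma)
      dZs <- if (kSub > 0)
        (1 - alphaUsed) * .focalGradLogits(ps, encB$sub, state@gamma)
        else matrix(0, length(b), 0L)
      bw <- .tinyBackward(dZb, dZs, params, fw$cache)
      upd <- .adamStep(params, bw$grads, opt, lrEp,
        weightDecay = weightDecay)
      params <- upd$params; opt <- upd$opt
      stepN <- stepN + 1L
      epLoss <- epLoss + ls$loss * length(b)
      stepLog[[stepN]] <- data.frame(step = stepN, epoch = ep,
        flBase = ls$flBase, flSub = ls$flSub, alphaUsed = alphaUsed,
        alphaNext = state@alpha)
    }
    # validation with the weights at epoch end and the current alpha
    vfw <- .tinyForward(valStack, params)
    vpb <- .softmaxRows(vfw$baseLogits)
    vps <- .softmaxRows(vfw$subLogits)
    vFlBase <- focalLoss(vpb, valEnc$base, state@gamma)
    withSub <- which(!is.na(valEnc$sub))
    vFlSub <- if (length(withSub))
      focalLoss(vps[withSub, , drop = FALSE], valEnc$sub[withSub],
        state@gamma) else 0
    vLoss <- totalLoss(vFlBase, vFlSub, state@alpha)
    vMasked <- maskSubtypeProbs(vpb, vps, hier)
    vBaseAcc <- mean(max.col(vpb, "first") == valEnc$base)
    vSubAcc <- if (length(withSub))
      mean(max.col(vMasked[withSub, , drop = FALSE], "first") ==
        valEnc$sub[withSub]) else NA_real_
    epochLog[[ep]] <- data.frame(epoch = ep,
      trainLoss = epLoss / length(trIdx), valLoss = vLoss,
      valBaseAcc = vBaseAcc, valSubAcc = vSubAcc, alpha = state@alpha)
    if (verbose)
      message(sprintf(
        "epoch %d: train %.4f, val %.4f, base acc %.3f, sub acc %.3f, alpha %.3f",
        ep, epLoss / length(trIdx), vLoss, vBaseAcc, vSubAcc, state@alpha))
    if (vLoss < best$loss - 1e-9) {
      best <- list(loss = vLoss, params = params, epoch = ep)
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest >= earlyStopPatience) break
    }
  }

  temps <- .fitTemperatures(best$params, valStack, valEnc)

  new("CellTypeModel", backbone = config$backbone, params = best$params,
    cfg = list(h = h, w = w, kBase = kBase, kSub = kSub,
      featureDim = config$featureDim, f1 = config$f1, f2 = config$f2,
      seed = as.integer(seed), bestEpoch = best$epoch,
      tempBase = temps[1L], tempSub = temps[2L]),
    hierarchy = hier, hierFingerprint = hierFingerprint(hier),
    mapFingerprint = mapFingerprint(map), lossState = state,
    trainLog = do.call(rbind, epochLog), stepLog = do.call(rbind, stepLog))
}



# Post-hoc temperature calibration on the validation split: one temperature
# per head, fitted by minimizing validation NLL (Guo-style temperature
# scaling). Stored in the checkpoint and applied at inference; per-head
# argmax (hence accuracy) is unaffected, but probabilities — and therefore
# the rare-population score — become calibrated.
.fitTemperatures <- function(params, valStack, valEnc) {
  if (dim(valStack)[1L] == 0L) return(c(1, 1))
  fw <- .tinyForward(valStack, params)
  nll <- function(T, logits, y) {
    ok <- !is.na(y)
    if (!any(ok) || ncol(logits) == 0L) return(NA_real_)
    p <- .softmaxRows(logits[ok, , drop = FALSE] / T)
    -mean(log(pmax(p[cbind(seq_len(sum(ok)), y[ok])], 1e-12)))
  }
  fit <- function(logits, y) {
    if (is.na(nll(1, logits, y))) return(1)
    stats::optimize(nll, c(0.05, 20), logits = logits, y = y)$minimum
  }
  c(fit(fw$baseLogits, valEnc$base), fit(fw$subLogits, valEnc$sub))
}

# ---- metrics ----

# confusion matrix, rows = truth, cols = prediction (NA predictions allowed
# and counted in an extra "<none>" column when present)
.confusion <- function(true, pred, levels) {
  predF <- factor(ifelse(is.na(pred), "<none>", pred),
    levels = c(levels, if (anyNA(pred)) "<none>"))
  table(truth = factor(true, levels = levels), prediction = predF)
}

# average precision (area under the precision-recall curve, step-wise)
.averagePrecision <- function(scores, positive) {
  nPos <- sum(positive)
  if (nPos == 0L) return(NA_real_)
  ord <- order(-scores)
  tp <- cumsum(positive[ord])
  prec <- tp / seq_along(tp)
  rec <- tp / nPos
  dRec <- diff(c(0, rec))
  sum(prec * dRec)
}

.levelMetrics <- function(trueIdx, predIdx, probs, classNames) {
  k <- length(classNames)
  conf <- .confusion(classNames[trueIdx],
    ifelse(is.na(predIdx), NA_character_, classNames[predIdx]), classNames)
  core <- conf[, seq_len(k), drop = FALSE]
  support <- rowSums(conf)
  tp <- diag(core)
  predTot <- colSums(core)
  prec <- ifelse(predTot > 0, tp / predTot, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- support > 0
  ap <- vapply(seq_len(k), function(c)
    .averagePrecision(probs[, c], trueIdx == c), numeric(1))
  list(
    accuracy = mean(!is.na(predIdx) & predIdx == trueIdx),
    macroPrecision = mean(prec[present]),
    macroRecall = mean(rec[present]),
    macroF1 = mean(f1[present]),
    macroAUPRC = mean(ap[present], na.rm = TRUE),
    perClass = data.frame(class = classNames, support = as.integer(support),
      precision = prec, recall = rec, f1 = f1, auprc = ap),
    confusion = conf)
}

#' Evaluate a trained model
#'
#' Computes accuracy, macro precision/recall/F1 and macro AUPRC at both
#' levels from the model's masked hierarchical predictions. Subtype metrics
#' cover only cells with a subtype label; base-level AUPRC uses the base
#' probability matrix and subtype AUPRC the masked subtype probabilities.
#' Classes with zero truth support are excluded from the macro averages.
#'
#' @param model a [CellTypeModel-class].
#' @param sce labeled query SingleCellExperiment (aligned to the model's
#'   panel, `"lognorm"` assay).
#' @param map the [PixelMap-class] the model was trained with.
#' @param baseLabels,subLabels truth labels (default from colData).
#' @return list with components `base` and `subtype`, each holding
#'   `accuracy`, `macroPrecision`, `macroRecall`, `macroF1`, `macroAUPRC`,
#'   a `perClass` table and a `confusion` matrix.
#' @export
evaluateClassifier <- function(model, sce, map,
    baseLabels = sce$baseLabel, subLabels = sce$subLabel) {
  .checkCompatible(model, map)
  hier <- model@hierarchy
  enc <- encodeLabels(hier, baseLabels, subLabels)
  stack <- renderImages(sce, map)
  pr <- .modelProbs(model, stack)
  masked <- maskSubtypeProbs(pr$base, pr$sub, hier)
  predBase <- max.col(pr$base, "first")
  predSub <- .maskedArgmax(masked)
  baseM <- .levelMetrics(enc$base, predBase, pr$base, baseTypes(hier))
  withSub <- which(!is.na(enc$sub))
  subM <- if (length(withSub))
    .levelMetrics(enc$sub[withSub], predSub[withSub],
      masked[withSub, , drop = FALSE], subTypes(hier))
    else NULL
  list(base = baseM, subtype = subM)
}

# argmax of masked subtype rows; all-zero rows (terminal base) -> NA
.maskedArgmax <- function(masked) {
  if (ncol(masked) == 0L) return(rep(NA_integer_, nrow(masked)))
  idx <- max.col(masked, "first")
  idx[rowSums(masked) == 0] <- NA_integer_
  idx
}

#' Write the per-epoch training log
#' @param model a [CellTypeModel-class].
#' @param path CSV path.
#' @export
writeTrainLog <- function(model, path) {
  utils::write.csv(model@trainLog, path, row.names = FALSE)
  invisible(path)
}

#' Write an evaluation report
#'
#' Serializes the scalar metrics of both levels as JSON and the confusion
#' matrices as TSV files (`<prefix>.metrics.json`,
#' `<prefix>.confusion.<level>.tsv`).
#'
#' @param report output of [evaluateClassifier()].
#' @param prefix output path prefix.
#' @export
writeMetricsReport <- function(report, prefix) {
  scalars <- lapply(report, function(lv) {
    if (is.null(lv)) return(NULL)
    lv[c("accuracy", "macroPrecision", "macroRecall", "macroF1",
      "macroAUPRC")]
  })
  jsonlite::write_json(scalars[!vapply(scalars, is.null, logical(1))],
    paste0(prefix, ".metrics.json"), auto_unbox = TRUE, digits = NA)
  for (lv in names(report)) {
    if (is.null(report[[lv]])) next
    conf <- as.data.frame.matrix(report[[lv]]$confusion)
    utils::write.table(cbind(truth = rownames(conf), conf),
      paste0(prefix, ".confusion.", lv, ".tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}
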