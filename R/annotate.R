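#' Annotate query cells with a trained model
#'
#' Aligns the query to the model's gene panel (zero-filling missing genes
#' and recording the coverage percentage), renders images with the training
#' pixel map, and predicts hierarchically: the base head gives the lineage,
#' probability masking restricts the subtype head to that lineage, and
#' terminal-leaf lineages yield base-only labels. Every cell also receives a
#' rare-population score (see [rareScore()]) and a novelty flag.
#'
#' @param sce query SingleCellExperiment with a `"lognorm"` assay.
#' @param model a [CellTypeModel-class].
#' @param map the [PixelMap-class] the model was trained with.
#' @param correction optional batch-correction hook applied to the aligned
#'   query (a function SCE -> SCE; default [identityCorrection()]).
#' @param coverageFloor warn when panel coverage (percent) falls below this.
#' @param tauBase,tauScore novelty-flag thresholds, see [flagNovel()].
#' @return the aligned query with colData columns `baseLabel`, `baseProb`,
#'   `subLabel` (`NA` for terminal lineages), `subProb`, `rareScore`,
#'   `novelFlag`, matrix columns `baseProbs`, `subProbsRaw`,
#'   `subProbsMasked`, and `metadata()$coverage` (percent).
#' @export
annotateCells <- function(sce, model, map, correction = identityCorrection,
    coverageFloor = 50, tauBase = 0.8, tauScore = 0.4) {
  hier <- model@hierarchy
  .checkCompatible(model, map)
  aligned <- alignToPanel(sce, panelGenes(map))
  coverage <- metadata(aligned)$coverage
  if (coverage < coverageFloor)
    warning(sprintf("gene coverage %.1f%% below floor %.1f%%; ",
      coverage, coverageFloor),
      "predictions rely on random-masking robustness")
  aligned <- correction(aligned)
  stack <- renderImages(aligned, map)
  pr <- .modelProbs(model, stack)
  masked <- maskSubtypeProbs(pr$base, pr$sub, hier)

  bIdx <- max.col(pr$base, "first")
  sIdx <- .maskedArgmax(masked)
  baseProb <- pr$base[cbind(seq_len(nrow(pr$base)), bIdx)]
  subProb <- ifelse(is.na(sIdx), NA_real_,
    masked[cbind(seq_len(nrow(masked)), ifelse(is.na(sIdx), 1L, sIdx))])
  score <- rareScore(pr$base, masked, hier)
  dec <- decodeLabels(hier, list(base = bIdx, sub = sIdx))

  cd <- colData(aligned)
  cd$baseLabel <- dec$base
  cd$baseProb <- baseProb
  cd$subLabel <- dec$sub
  cd$subProb <- subProb
  cd$rareScore <- score
  cd$novelFlag <- flagNovel(baseProb, score, tauBase, tauScore)
  colnames(pr$base) <- baseTypes(hier)
  if (ncol(masked)) colnames(masked) <- colnames(pr$sub) <- subTypes(hier)
  cd$baseProbs <- pr$base
  cd$subProbsRaw <- pr$sub
  cd$subProbsMasked <- masked
  colData(aligned) <- cd
  aligned
}

#' Rare/novel-population score
#'
#' The signature of a population absent from the training taxonomy is a
#' cell placed confidently in a lineage whose subtypes all fit it poorly:
#' `score = max(baseProbs) - max(maskedSubProbs)`, in \[-1, 1\]. Cells of
#' well-trained subtypes score near 0 (both confidences high); cells of an
#' unseen subtype keep the lineage confidence but spread the masked subtype
#' distribution, scoring high. Terminal-leaf predictions have no subtype
#' uncertainty to measure and score 0 by convention.
#'
#' @param baseProbs cells x nBase probability matrix (or vector).
#' @param maskedSubProbs matching masked subtype probabilities.
#' @param hier the [CellTypeHierarchy-class].
#' @return numeric score per cell.
#' @export
rareScore <- function(baseProbs, maskedSubProbs, hier) {
  if (!is.matrix(baseProbs)) {
    baseProbs <- matrix(baseProbs, 1L)
    maskedSubProbs <- matrix(maskedSubProbs, 1L)
  }
  bIdx <- max.col(baseProbs, "first")
  terminal <- isTerminal(hier, baseTypes(hier)[bIdx])
  maxBase <- baseProbs[cbind(seq_len(nrow(baseProbs)), bIdx)]
  maxSub <- if (ncol(maskedSubProbs))
    matrixStats::rowMaxs(maskedSubProbs) else rep(0, nrow(baseProbs))
  ifelse(terminal, 0, maxBase - maxSub)
}

#' Flag candidate novel populations
#'
#' A cell is flagged when the lineage itself is confident
#' (`maxBaseProb >= tauBase`) *and* the rare score is high
#' (`score >= tauScore`). Both thresholds are tunable; the continuous score
#' is always reported alongside so users can re-threshold.
#'
#' @param maxBaseProb per-cell maximum base-type probability.
#' @param score per-cell [rareScore()].
#' @param tauBase,tauScore thresholds in \[0,1\].
#' @return logical vector.
#' @export
flagNovel <- function(maxBaseProb, score, tauBase = 0.8, tauScore = 0.4) {
  if (tauBase < 0 || tauBase > 1 || tauScore < 0 || tauScore > 1)
    stop("thresholds must be in [0,1]")
  maxBaseProb >= tauBase & score >= tauScore
}

#' Write annotation results
#'
#' Writes the per-cell annotation table as TSV (cell id, labels,
#' probabilities, rare score, novelty flag).
#'
#' @param sce annotated SingleCellExperiment from [annotateCells()].
#' @param path output TSV path.
#' @export
writeAnnotation <- function(sce, path) {
  df <- data.frame(cell = colnames(sce),
    baseLabel = sce$baseLabel, baseProb = sce$baseProb,
    subLabel = sce$subLabel, subProb = sce$subProb,
    rareScore = sce$rareScore, novelFlag = sce$novelFlag)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
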