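#' Construct a synthetic scenario
#'
#' @param hierarchy a [CellTypeHierarchy-class].
#' @param nCellsPerSubtype cells per leaf population (each subtype and each
#'   terminal base type).
#' @param nGenes total genes.
#' @param lineageBlockSize,subtypeBlockSize marker genes per lineage block /
#'   per subtype block. Blocks are disjoint.
#' @param lineageEffect,subtypeEffect marker elevation in log units: cells of
#'   a lineage have the lineage block's mean multiplied by
#'   `exp(lineageEffect)`; cells of a subtype additionally have their subtype
#'   block multiplied by `exp(subtypeEffect)`.
#' @param dropoutRate independent per-entry zeroing probability in \[0,1).
#' @param dispersion negative-binomial dispersion of baseline counts
#'   (variance = mu + dispersion * mu^2).
#' @param batchShifts list of numeric length-`nGenes` log-scale offsets, one
#'   per batch (empty list: single batch, no shift).
#' @param holdoutSubtypes subtype names to withhold from training splits.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a [SyntheticScenario-class].
#' @export
syntheticScenario <- function(hierarchy, nCellsPerSubtype = 120L,
    nGenes = 200L, lineageBlockSize = 5L, subtypeBlockSize = 5L,
    lineageEffect = 2.0, subtypeEffect = 1.5, dropoutRate = 0.3,
    dispersion = 0.5, batchShifts = list(), holdoutSubtypes = character(0),
    seed = 7L) {
  new("SyntheticScenario", hierarchy = hierarchy,
    nCellsPerSubtype = as.integer(nCellsPerSubtype),
    nGenes = as.integer(nGenes),
    lineageBlockSize = as.integer(lineageBlockSize),
    subtypeBlockSize = as.integer(subtypeBlockSize),
    lineageEffect = lineageEffect, subtypeEffect = subtypeEffect,
    dropoutRate = dropoutRate, dispersion = dispersion,
    batchShifts = batchShifts, holdoutSubtypes = as.character(holdoutSubtypes),
    seed = as.integer(seed))
}

#' The standard synthetic test scenario
#'
#' The canonical small fixture used throughout the package's tests and
#' examples: three immune-like lineages (T and B with three subtypes each,
#' NK terminal), 200 genes, 120 cells per leaf population, 5-gene marker
#' blocks with lineage effect 2.0 and subtype effect 1.5 log units, 30%
#' dropout, seed 7. Small enough that the full layout -> train -> annotate
#' -> explain pipeline runs in minutes on one CPU.
#'
#' @param ... overrides passed to [syntheticScenario()].
#' @return a [SyntheticScenario-class].
#' @export
standardScenario <- function(...) {
  h <- CellTypeHierarchy(list(
    "T" = c("CD4 T", "CD8 T", "MAIT"),
    "B" = c("Naive B", "Memory B", "Plasma"),
    "NK" = character(0)))
  syntheticScenario(hierarchy = h, ...)
}

#' Generate synthetic labeled single-cell data
#'
#' Draws baseline counts per gene from a negative binomial around log-normal
#' gene means, elevates the lineage marker block for every cell of that
#' lineage and additionally the subtype block for cells of that subtype,
#' applies independent dropout, and (optionally) per-batch log-scale shifts.
#' Terminal base types receive only their lineage block. The planted marker
#' map is stored in `metadata()$markers` for downstream assertions.
#'
#' @param scn a [SyntheticScenario-class].
#' @return SingleCellExperiment (genes x cells) with a `"counts"` assay,
#'   colData columns `baseLabel`, `subLabel` (`NA` for terminal-lineage
#'   cells) and `batch`, and `metadata()$markers` — a list with `lineage`
#'   and `subtype` named lists of marker gene names.
#' @export
simulateCells <- function(scn) {
  h <- scn@hierarchy
  set.seed(scn@seed)
  genes <- sprintf("G%04d", seq_len(scn@nGenes))

  # disjoint marker blocks: lineage blocks first, then subtype blocks
  ptr <- 0L
  takeBlock <- function(k) {
    blk <- genes[ptr + seq_len(k)]; ptr <<- ptr + k; blk
  }
  lineageMarkers <- lapply(baseTypes(h), function(b)
    takeBlock(scn@lineageBlockSize))
  names(lineageMarkers) <- baseTypes(h)
  subtypeMarkers <- lapply(subTypes(h), function(s)
    takeBlock(scn@subtypeBlockSize))
  names(subtypeMarkers) <- subTypes(h)

  # leaf populations: every subtype, plus each terminal base
  leaves <- rbind(
    do.call(rbind, lapply(subTypes(h), function(s)
      data.frame(base = parentOf(h, s), sub = s))),
    if (any(isTerminal(h, baseTypes(h))))
      data.frame(base = baseTypes(h)[isTerminal(h, baseTypes(h))],
        sub = NA_character_))
  nPop <- nrow(leaves)
  nCells <- nPop * scn@nCellsPerSubtype
  if (nCells == 0L) {
    mat <- matrix(0, scn@nGenes, 0, dimnames = list(genes, character(0)))
    sce <- makeSCE(mat, "counts")
    sce$baseLabel <- character(0); sce$subLabel <- character(0)
    sce$batch <- integer(0)
    metadata(sce)$markers <- list(lineage = lineageMarkers,
      subtype = subtypeMarkers)
    return(sce)
  }

  baseMu <- exp(rnorm(scn@nGenes, log(16), 0.6))
  names(baseMu) <- genes
  nBatch <- max(1L, length(scn@batchShifts))

  counts <- matrix(0L, scn@nGenes, nCells, dimnames = list(genes, NULL))
  baseLab <- character(nCells); subLab <- character(nCells)
  batch <- rep_len(seq_len(nBatch), nCells)
  col <- 0L
  for (p in seq_len(nPop)) {
    mu <- baseMu
    mu[lineageMarkers[[leaves$base[p]]]] <-
      mu[lineageMarkers[[leaves$base[p]]]] * exp(scn@lineageEffect)
    if (!is.na(leaves$sub[p]))
      mu[subtypeMarkers[[leaves$sub[p]]]] <-
        mu[subtypeMarkers[[leaves$sub[p]]]] * exp(scn@subtypeEffect)
    for (i in seq_len(scn@nCellsPerSubtype)) {
      col <- col + 1L
      m <- mu
      if (length(scn@batchShifts))
        m <- m * exp(scn@batchShifts[[batch[col]]])
      counts[, col] <- rnbinom(scn@nGenes, mu = m, size = 1 / scn@dispersion)
      baseLab[col] <- leaves$base[p]
      subLab[col] <- leaves$sub[p]
    }
  }
  if (scn@dropoutRate > 0) {
    keep <- matrix(rbinom(length(counts), 1L, 1 - scn@dropoutRate),
      nrow(counts), ncol(counts))
    counts <- counts * keep
  }
  colnames(counts) <- sprintf("cell%05d", seq_len(nCells))

  sce <- makeSCE(counts, "counts")
  sce$baseLabel <- baseLab
  sce$subLabel <- ifelse(is.na(subLab), NA_character_, subLab)
  sce$batch <- batch
  metadata(sce)$markers <- list(lineage = lineageMarkers,
    subtype = subtypeMarkers)
  metadata(sce)$scenario <- scn
  sce
}

#' Split generated cells into training and held-out novel populations
#'
#' @param sce output of [simulateCells()].
#' @param holdoutSubtypes subtype names treated as unseen novel populations;
#'   defaults to the scenario's `holdoutSubtypes`.
#' @return list with SingleCellExperiments `train` and `holdout`.
#' @export
splitHoldout <- function(sce, holdoutSubtypes = NULL) {
  if (is.null(holdoutSubtypes)) {
    scn <- metadata(sce)$scenario
    holdoutSubtypes <- if (is.null(scn)) character(0) else scn@holdoutSubtypes
  }
  isHold <- !is.na(sce$subLabel) & sce$subLabel %in% holdoutSubtypes
  list(train = sce[, !isHold], holdout = sce[, isHold])
}

setMethod("show", "SyntheticScenario", function(object) {
  cat("SyntheticScenario:", nBaseTypes(object@hierarchy), "base types /",
    nSubTypes(object@hierarchy), "subtypes,", object@nGenes, "genes,",
    object@nCellsPerSubtype, "cells per leaf population\n")
  cat("  effects (log units): lineage", object@lineageEffect, ", subtype",
    object@subtypeEffect, "; dropout", object@dropoutRate, "; seed",
    object@seed, "\n")
})
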