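suppressPackageStartupMessages({
  library(SingleCellExperiment)   # assay/colData/metadata accessors
})

# Shared fixtures. Heavy objects (the standard synthetic scenario rendered
# and trained end-to-end) are built once per test run and cached in this
# environment; individual tests only read them.

.fixtures <- new.env(parent = emptyenv())

tinyHier <- function() {
  CellTypeHierarchy(list("T" = c("CD4 T", "CD8 T"), "NK" = character(0)))
}

# small labeled SCE with arbitrary counts
toySCE <- function(nGenes = 12L, nCells = 8L, seed = 42L) {
  set.seed(seed)
  m <- matrix(rpois(nGenes * nCells, 5), nGenes, nCells,
    dimnames = list(sprintf("g%02d", seq_len(nGenes)),
      sprintf("c%02d", seq_len(nCells))))
  makeSCE(m, "counts")
}

# Standard-scenario data, extended with a fresh query draw: 160 cells per
# leaf population, of which the first 120 (the standard scenario size) are
# the training pool and the remaining 40 form held-out query cells from the
# same generative model. The pixel map is fitted on the training pool only.
stdData <- function() {
  if (!is.null(.fixtures$std)) return(.fixtures$std)
  scn <- standardScenario(nCellsPerSubtype = 160L)
  sce <- logNormalize(simulateCells(scn))
  perLeaf <- 160L
  nPop <- ncol(sce) / perLeaf
  train <- unlist(lapply(seq_len(nPop) - 1L, function(p)
    p * perLeaf + 1:120))
  test <- setdiff(seq_len(ncol(sce)), train)
  map <- fitPixelMap(sce[, train], gridDim = c(32L, 32L), seed = 3L)
  .fixtures$std <- list(scn = scn, sce = sce, map = map,
    train = train, test = test)
  .fixtures$std
}

stdConfig <- function() {
  classifierConfig(featureDim = 128L, f1 = 16L, f2 = 32L)
}

# the main trained checkpoint on the standard scenario, cached
stdModel <- function() {
  if (!is.null(.fixtures$model)) return(.fixtures$model)
  d <- stdData()
  .fixtures$model <- trainClassifier(d$sce[, d$train], d$map,
    d$scn@hierarchy, epochs = 80L, batchSize = 64L, lr = 3e-3,
    seed = 5L, maskFraction = 0.3, earlyStopPatience = 80L,
    config = stdConfig())
  .fixtures$model
}

# Model trained with one subtype withheld from the cells, the taxonomy and
# the pixel-map reference: a population is novel exactly when the reference
# knows nothing of it.
holdoutModel <- function() {
  if (!is.null(.fixtures$holdout)) return(.fixtures$holdout)
  d <- stdData()
  keep <- d$train[is.na(d$sce$subLabel[d$train]) |
    d$sce$subLabel[d$train] != "MAIT"]
  map <- fitPixelMap(d$sce[, keep], gridDim = c(32L, 32L), seed = 3L)
  model <- trainClassifier(d$sce[, keep], map,
    dropSubtype(d$scn@hierarchy, "MAIT"), epochs = 60L, batchSize = 64L,
    lr = 3e-3, seed = 5L, maskFraction = 0.3, earlyStopPatience = 60L,
    config = stdConfig())
  .fixtures$holdout <- list(model = model, map = map)
  .fixtures$holdout
}

# rank-sum AUROC, independent of the package's dependencies
aurocOf <- function(scorePos, scoreNeg) {
  r <- rank(c(scorePos, scoreNeg))
  (sum(r[seq_along(scorePos)]) -
    length(scorePos) * (length(scorePos) + 1) / 2) /
    (length(scorePos) * length(scoreNeg))
}

# a deterministic untrained model for contract tests (no training needed)
freshModel <- function(map, hier, seed = 1L) {
  params <- scImageHier:::.initTinyCnn(map@gridDim[1L], map@gridDim[2L],
    16L, nBaseTypes(hier), nSubTypes(hier), f1 = 4L, f2 = 4L, seed = seed)
  new("CellTypeModel", backbone = "tiny_cnn", params = params,
    cfg = list(h = map@gridDim[1L], w = map@gridDim[2L],
      kBase = nBaseTypes(hier), kSub = nSubTypes(hier),
      featureDim = 16L, f1 = 4L, f2 = 4L, seed = seed, bestEpoch = 0L),
    hierarchy = hier, hierFingerprint = hierFingerprint(hier),
    mapFingerprint = mapFingerprint(map), lossState = lossState(),
    trainLog = data.frame(), stepLog = data.frame())
}

# exhaustive minimum-cost injection oracle for small assignment instances
bruteForceAssign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  best <- Inf
  rec <- function(g, used, acc) {
    if (acc >= best) return()
    if (g > n) { best <<- acc; return() }
    for (p in seq_len(m)) if (!used[p]) {
      used[p] <- TRUE
      rec(g + 1L, used, acc + cost[g, p])
      used[p] <- FALSE
    }
  }
  rec(1L, rep(FALSE, m), 0)
  unname(best)
}

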