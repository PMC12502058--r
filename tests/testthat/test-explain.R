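# hand-built model whose base-class-1 score depends (monotonically) only on
# the pixel at (1,1): identity convs, pooled cell (1,1), direct readout
probeModel <- function() {
  h <- CellTypeHierarchy(list(p = c("u", "v"), q = character(0)))
  co <- rbind(gA = c(0, 0), gB = c(3, 3))
  assign <- data.frame(gene = c("gA", "gB"), row = c(1L, 4L),
    col = c(1L, 4L))
  map <- new("PixelMap", gridDim = c(4L, 4L), assignment = assign,
    geneMin = c(gA = 0, gB = 0), geneMax = c(gA = 1, gB = 1),
    coords = co, method = "tsne", perplexity = 5, seed = 1L,
    nChannels = 1L)
  params <- scImageHier:::.initTinyCnn(4L, 4L, 4L, 2L, 2L, f1 = 2L,
    f2 = 2L, seed = 1L)
  for (nm in names(params)) params[[nm]][] <- 0
  params$Wc1[5, 1] <- 1          # centre tap of the 3x3 kernel, channel 1
  params$Wc2[5, 1] <- 1          # centre tap on channel 1 (rows 1:9)
  # pooled grid is 2x2 with 2 channels; flat layout: pixels then channels
  params$Wd[1, 1] <- 1           # pooled cell (1,1), channel 1 -> feature 1
  params$Wb[1, 1] <- 1           # feature 1 -> base class 1 logit
  list(map = map, hier = h, params = params)
}

wrapModel <- function(p) {
  new("CellTypeModel", backbone = "tiny_cnn", params = p$params,
    cfg = list(h = 4L, w = 4L, kBase = 2L, kSub = 2L, featureDim = 4L,
      f1 = 2L, f2 = 2L, seed = 1L, bestEpoch = 0L),
    hierarchy = p$hier, hierFingerprint = hierFingerprint(p$hier),
    mapFingerprint = mapFingerprint(p$map), lossState = lossState(),
    trainLog = data.frame(), stepLog = data.frame())
}

test_that("occlusion attributions equal the two-forward-pass definition on
           every pixel", {
  d <- stdData()
  h <- d$scn@hierarchy
  params <- scImageHier:::.initTinyCnn(32L, 32L, 16L, nBaseTypes(h),
    nSubTypes(h), f1 = 4L, f2 = 4L, seed = 3L)
  model <- new("CellTypeModel", backbone = "tiny_cnn", params = params,
    cfg = list(h = 32L, w = 32L), hierarchy = h,
    hierFingerprint = hierFingerprint(h),
    mapFingerprint = mapFingerprint(d$map), lossState = lossState(),
    trainLog = data.frame(), stepLog = data.frame())
  stack <- renderImages(d$sce[, 1:3], d$map)
  maps <- attributePixels(model, stack, "base", 1L, "occlusion",
    map = d$map)
  # definitional oracle: score(original) - score(one pixel zeroed),
  # recomputed here pixel by pixel with plain forward passes
  score <- function(s) scImageHier:::.classScore(model, s, "base", 1L)
  s0 <- score(stack)
  set.seed(8)
  pix <- cbind(sample(32, 40, TRUE), sample(32, 40, TRUE))
  for (i in 1:3) {
    for (k in seq_len(nrow(pix))) {
      s2 <- stack[i, , , drop = FALSE]
      s2[1, pix[k, 1], pix[k, 2]] <- 0
      expect_equal(maps[i, pix[k, 1], pix[k, 2]], s0[i] - score(s2),
        tolerance = 1e-12)
    }
  }
  expect_error(attributePixels(model, stack[0, , , drop = FALSE],
    "base", 1L, "occlusion", map = d$map), "empty")
})

test_that("a model that ignores its input gets all-zero occlusion
           attributions", {
  p <- probeModel()
  p$params$Wb[] <- 0             # heads now constant
  p$params$Wd[] <- 0
  model <- wrapModel(p)
  stack <- array(runif(2 * 4 * 4), c(2, 4, 4))
  maps <- attributePixels(model, stack, "base", 1L, "occlusion",
    map = p$map)
  expect_true(all(maps == 0))
})

test_that("a single-pixel probe model attributes only its pixel, under
           both back-ends", {
  p <- probeModel()
  model <- wrapModel(p)
  stack <- array(0, c(1, 4, 4))
  stack[1, 1, 1] <- 0.8          # gA's pixel drives the class score
  stack[1, 4, 4] <- 0.5          # gB's pixel is ignored by construction
  occ <- attributePixels(model, stack, "base", 1L, "occlusion",
    map = p$map)
  expect_gt(occ[1, 1, 1], 0)
  expect_equal(occ[1, 4, 4], 0)
  bg <- array(0, c(3, 4, 4))     # zero background
  sh <- attributePixels(model, stack, "base", 1L, "shap",
    background = bg, nBackground = 20L, seed = 2L)
  expect_gt(sh[1, 1, 1], 0)
  expect_equal(sh[1, 4, 4], 0)
  expect_equal(sum(sh[1, , ] != 0), 1L)
})

test_that("pixel attributions fold back to genes through the map", {
  p <- probeModel()
  maps <- array(0, c(2, 4, 4))
  maps[1, 1, 1] <- 0.7           # gA, cell 1
  maps[2, 1, 1] <- -0.7
  maps[1, 2, 2] <- 99            # unassigned pixel: ignored
  tab <- foldToGenes(maps, p$map, class = "p", level = "base")
  expect_equal(tab$meanAbsAttribution[tab$gene == "gA"], 0.7)
  expect_equal(tab$meanSignedAttribution[tab$gene == "gA"], 0)
  expect_equal(tab$meanAbsAttribution[tab$gene == "gB"], 0)
  expect_equal(tab$nCells, c(2L, 2L))
  expect_error(foldToGenes(array(0, c(1, 3, 3)), p$map), "shape")
})

test_that("top-gene ranking is deterministic with name tie-breaks", {
  tab <- data.frame(class = "c", level = "base",
    gene = c("gB", "gA", "gC"),
    meanAbsAttribution = c(0.5, 0.5, 0.9),
    meanSignedAttribution = 0, nCells = 3L)
  expect_equal(topGenes(tab, "c", "base", 2L), c("gC", "gA"))
  expect_equal(topGenes(tab, "c", "base", 10L), c("gC", "gA", "gB"))
  expect_error(topGenes(tab, "nope", "base"), "not present")
})

test_that("planted subtype markers dominate the importance ranking of a
           trained model, and lineage markers mark the base class", {
  d <- stdData()
  model <- stdModel()
  mk <- metadata(d$sce)$markers
  test <- d$sce[, d$test]
  for (s in c("CD8 T", "Plasma")) {
    tab <- geneImportance(model, test, d$map, s, level = "subtype",
      method = "occlusion", maxCells = 25L)
    top10 <- topGenes(tab, s, "subtype", 10L)
    expect_gte(length(intersect(top10, mk$subtype[[s]])), 3L)
  }
  # lineage-shared markers rank highly for the base class
  tabT <- geneImportance(model, test, d$map, "T", level = "base",
    method = "occlusion", maxCells = 25L)
  topT <- topGenes(tabT, "T", "base", 10L)
  expect_gte(length(intersect(topT, mk$lineage[["T"]])), 3L)
})

test_that("expected-gradients attributions agree in rank with occlusion on
           a trained model", {
  d <- stdData()
  model <- stdModel()
  test <- d$sce[, d$test]
  bg <- renderImages(d$sce[, d$train[seq(1, 400, by = 8)]], d$map)
  tabS <- geneImportance(model, test, d$map, "CD8 T", level = "subtype",
    method = "shap", background = bg, nBackground = 30L, maxCells = 10L,
    seed = 4L)
  tabO <- geneImportance(model, test, d$map, "CD8 T", level = "subtype",
    method = "occlusion", maxCells = 10L)
  topS <- topGenes(tabS, "CD8 T", "subtype", 10L)
  topO <- topGenes(tabO, "CD8 T", "subtype", 10L)
  expect_gte(length(intersect(topS, topO)), 5L)
  expect_true(all(is.finite(tabS$meanAbsAttribution)))
})
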