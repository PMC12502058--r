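assignCost <- function(assign, coords, gridDim) {
  sc <- scImageHier:::.scaleToGrid(coords, gridDim)
  sum((sc[, 1] - (assign$col - 1))^2 + (sc[, 2] - (assign$row - 1))^2)
}

test_that("pixel assignment achieves the exhaustive minimum cost on random
           small instances", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(2:6, 1)
    gd <- sample(list(c(2L, 2L), c(3L, 3L), c(2L, 4L), c(3L, 2L)), 1)[[1]]
    while (prod(gd) < n) gd <- c(3L, 3L)
    coords <- matrix(rnorm(2 * n), n, 2,
      dimnames = list(paste0("g", 1:n), NULL))
    a <- assignPixels(coords, gd)
    # injective, in range
    expect_false(anyDuplicated(paste(a$row, a$col)) > 0)
    expect_true(all(a$row >= 1 & a$row <= gd[1] & a$col >= 1 &
      a$col <= gd[2]))
    # optimal total cost equals brute-force enumeration
    sc <- scImageHier:::.scaleToGrid(coords, gd)
    centers <- cbind(rep(0:(gd[2] - 1), each = gd[1]),
      rep(0:(gd[1] - 1), gd[2]))
    cost <- outer(sc[, 1], centers[, 1], "-")^2 +
      outer(sc[, 2], centers[, 2], "-")^2
    expect_equal(assignCost(a, coords, gd), bruteForceAssign(cost),
      tolerance = 1e-9)
  }
})

test_that("degenerate assignments behave as expected", {
  # one gene on a 1x1 grid gets that pixel
  a <- assignPixels(matrix(c(0.3, -1), 1, 2,
    dimnames = list("g1", NULL)), c(1L, 1L))
  expect_equal(a$row, 1L); expect_equal(a$col, 1L)
  # genes exactly on distinct pixel centers: zero total cost
  co <- rbind(g1 = c(0, 0), g2 = c(1, 0), g3 = c(0, 1), g4 = c(1, 1))
  a2 <- assignPixels(co, c(2L, 2L))
  expect_equal(assignCost(a2, co, c(2L, 2L)), 0, tolerance = 1e-12)
  # more genes than pixels is impossible
  expect_error(assignPixels(matrix(rnorm(10), 5, 2,
    dimnames = list(paste0("g", 1:5), NULL)), c(2L, 2L)), "pixels")
})

test_that("gene embedding is deterministic and respects correlation
           structure", {
  set.seed(9)
  # two blocks of mutually correlated genes
  nC <- 60L
  f1 <- rnorm(nC); f2 <- rnorm(nC)
  block <- function(f, k) t(sapply(seq_len(k), function(i)
    3 + f + rnorm(nC, 0, 0.3)))
  m <- rbind(block(f1, 15), block(f2, 15))
  m[m < 0] <- 0
  rownames(m) <- sprintf("g%02d", 1:30)
  colnames(m) <- sprintf("c%02d", 1:nC)
  sce <- makeSCE(m, "counts"); assay(sce, "lognorm") <- m

  e1 <- embedGenes(sce, "tsne", perplexityGrid = 5, seed = 4L)
  e2 <- embedGenes(sce, "tsne", perplexityGrid = 5, seed = 4L)
  expect_identical(e1$coords, e2$coords)

  d <- as.matrix(dist(e1$coords))
  within <- c(d[1:15, 1:15][upper.tri(diag(15))],
    d[16:30, 16:30][upper.tri(diag(15))])
  between <- d[1:15, 16:30]
  expect_lt(mean(within), mean(between))

  # perplexities beyond the t-SNE bound are refused with the bound named
  expect_error(embedGenes(sce, "tsne", perplexityGrid = 100), "bound")
})

test_that("tiny panels get a direct two-component layout", {
  m <- matrix(c(1, 5, 2, 6, 3, 4), 2, 3,
    dimnames = list(c("gA", "gB"), c("c1", "c2", "c3")))
  sce <- makeSCE(m, "counts"); assay(sce, "lognorm") <- m
  e <- embedGenes(sce, "tsne", seed = 1L)
  expect_equal(nrow(e$coords), 2L)
  expect_false(isTRUE(all.equal(e$coords[1, ], e$coords[2, ])))
})

test_that("rendering writes normalized intensities at assigned pixels and
           zero elsewhere, and read-back inverts it", {
  d <- stdData()
  map <- d$map
  expect_true(validObject(map))
  x <- assay(d$sce, "lognorm")
  stack <- renderImages(d$sce[, 1:5], map)
  expect_true(all(stack >= 0 & stack <= 1))
  # unassigned pixels are exactly zero
  occupied <- matrix(FALSE, map@gridDim[1], map@gridDim[2])
  occupied[cbind(map@assignment$row, map@assignment$col)] <- TRUE
  for (i in seq_len(dim(stack)[1]))
    expect_true(all(stack[i, , ][!occupied] == 0))
  # read-back recovers the clipped expression values
  v <- unrenderCell(stack[1, , ], map)
  expected <- pmin(pmax(x[names(v), 1], map@geneMin[names(v)]),
    map@geneMax[names(v)])
  expect_equal(v, expected, tolerance = 1e-12)
})

test_that("per-gene normalization hits the documented anchor points", {
  co <- rbind(gA = c(0, 0), gB = c(3, 0), gC = c(0, 3))
  assign <- assignPixels(co, c(4L, 4L))
  map <- new("PixelMap", gridDim = c(4L, 4L), assignment = assign,
    geneMin = c(gA = 0, gB = 1, gC = 2), geneMax = c(gA = 2, gB = 5,
      gC = 2), coords = co, method = "tsne", perplexity = 5,
    seed = 1L, nChannels = 3L)
  img <- renderCell(c(gA = 1, gB = 9, gC = 1.5), map)
  expect_equal(dim(img), c(4L, 4L, 3L))
  at <- function(g) img[assign$row[assign$gene == g],
    assign$col[assign$gene == g], 1]
  expect_equal(at("gA"), 0.5)      # midpoint of (0,2)
  expect_equal(at("gB"), 1)        # above the training max: clipped
  expect_equal(at("gC"), 0)        # constant gene renders 0
  expect_equal(img[, , 1], img[, , 2])
  # an all-zero cell renders as an all-zero image (gB min is 1 -> clip at 0)
  img0 <- renderCell(c(gA = 0, gB = 0, gC = 0), map)
  expect_true(all(img0 == 0))
  expect_error(renderCell(c(1, 2), map), "panel")
})

test_that("random masking zeroes the requested number of gene pixels,
           reproducibly", {
  d <- stdData()
  stack <- renderImages(d$sce[, 1:4], d$map)
  expect_identical(randomMask(stack, d$map, 0), stack)
  m1 <- randomMask(stack, d$map, 0.5, seed = 7L)
  m2 <- randomMask(stack, d$map, 0.5, seed = 7L)
  expect_identical(m1, m2)
  expect_false(identical(m1, randomMask(stack, d$map, 0.5, seed = 8L)))
  # exactly round(fraction * nGenes) assigned pixels are zeroed per image;
  # unassigned pixels are untouched (checked on an all-ones gene plane)
  idx <- cbind(d$map@assignment$row, d$map@assignment$col)
  nGenes <- nrow(idx)
  plane <- matrix(0, 32, 32); plane[idx] <- 1
  ones <- aperm(array(plane, c(32, 32, 3)), c(3, 1, 2))
  mk <- randomMask(ones, d$map, 0.5, seed = 1L)
  for (i in 1:3) {
    expect_equal(sum(mk[i, , ][idx] == 0), round(0.5 * nGenes))
    expect_true(all(mk[i, , ][-((idx[, 2] - 1) * 32 + idx[, 1])] ==
      ones[i, , ][-((idx[, 2] - 1) * 32 + idx[, 1])]))
  }
  expect_error(randomMask(stack, d$map, 1), "maskFraction")
})

test_that("pixel maps persist to text and reload identically; refits with
           one seed are byte-stable", {
  d <- stdData()
  dir1 <- tempfile(); dir2 <- tempfile()
  savePixelMap(d$map, dir1)
  map2 <- readPixelMap(dir1)
  expect_equal(map2@assignment, d$map@assignment)
  expect_equal(map2@geneMin, d$map@geneMin, tolerance = 1e-15)
  expect_equal(mapFingerprint(map2), mapFingerprint(d$map))

  refit <- fitPixelMap(d$sce[, d$train], gridDim = c(32L, 32L), seed = 3L)
  savePixelMap(refit, dir2)
  for (f in c("assignment.tsv", "normstats.tsv", "coords.tsv",
      "metadata.json"))
    expect_identical(readLines(file.path(dir1, f)),
      readLines(file.path(dir2, f)))
})
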