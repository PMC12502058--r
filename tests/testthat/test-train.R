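test_that("level metrics reproduce a hand-computed confusion matrix", {
  # truth/prediction pairs realizing the confusion matrix
  # [[2,0,0],[1,1,0],[0,0,2]] (rows = truth)
  trueIdx <- c(1L, 1L, 2L, 2L, 3L, 3L)
  predIdx <- c(1L, 1L, 1L, 2L, 3L, 3L)
  probs <- matrix(0, 6, 3)
  probs[cbind(1:6, predIdx)] <- 1
  m <- scImageHier:::.levelMetrics(trueIdx, predIdx, probs,
    c("x", "y", "z"))
  expect_equal(m$accuracy, 5 / 6, tolerance = 1e-12)
  expect_equal(m$macroPrecision, mean(c(2 / 3, 1, 1)), tolerance = 1e-12)
  expect_equal(m$macroRecall, mean(c(1, 1 / 2, 1)), tolerance = 1e-12)
  f1s <- c(2 * (2 / 3) / (5 / 3), 2 * 0.5 / 1.5, 1)
  expect_equal(m$macroF1, mean(f1s), tolerance = 1e-12)
  expect_equal(as.vector(m$confusion),
    as.vector(matrix(c(2, 1, 0, 0, 1, 0, 0, 0, 2), 3)))

  # a perfect predictor scores 1 everywhere
  p <- scImageHier:::.levelMetrics(trueIdx, trueIdx,
    { q <- matrix(0, 6, 3); q[cbind(1:6, trueIdx)] <- 1; q },
    c("x", "y", "z"))
  for (v in c("accuracy", "macroPrecision", "macroRecall", "macroF1",
      "macroAUPRC"))
    expect_equal(p[[v]], 1, info = v)

  # a label permutation on a balanced 2-class set scores 0
  z <- scImageHier:::.levelMetrics(c(1L, 1L, 2L, 2L), c(2L, 2L, 1L, 1L),
    matrix(0.5, 4, 2), c("x", "y"))
  expect_equal(z$accuracy, 0)
  expect_equal(z$macroF1, 0)
})

test_that("average precision matches a hand-worked small case", {
  # scores rank: pos, neg, pos, neg -> AP = (1/1 + 2/3) / 2
  ap <- scImageHier:::.averagePrecision(c(0.9, 0.8, 0.7, 0.1),
    c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(ap, (1 + 2 / 3) / 2, tolerance = 1e-12)
  expect_true(is.na(scImageHier:::.averagePrecision(c(0.2, 0.1),
    c(FALSE, FALSE))))
})

test_that("stratified splitting keeps every multi-member stratum in both
           partitions and is seed-stable", {
  enc <- list(base = rep(c(1L, 2L, 3L), c(20L, 20L, 1L)),
    sub = c(rep(c(1L, 2L), 10), rep(3:4, 10), NA))
  s1 <- scImageHier:::.stratifiedSplit(enc, 0.2, 9L)
  s2 <- scImageHier:::.stratifiedSplit(enc, 0.2, 9L)
  expect_identical(s1, s2)
  expect_length(intersect(s1$train, s1$val), 0L)
  expect_equal(sort(c(s1$train, s1$val)), seq_along(enc$base))
  # the singleton stratum (base 3) stays in training
  expect_true(41L %in% s1$train)
  for (s in 1:4)
    expect_true(any(enc$sub[s1$val] == s, na.rm = TRUE))
})

test_that("training validates its inputs", {
  d <- stdData()
  expect_error(trainClassifier(d$sce[, 1:30], d$map, d$scn@hierarchy,
    epochs = 0L), "epochs")
  expect_error(trainClassifier(d$sce[, 1:30], d$map, d$scn@hierarchy,
    epochs = 2L, validationFraction = 1.5), "validationFraction")
})

test_that("a short training run is bit-reproducible under one seed", {
  d <- stdData()
  sub <- d$sce[, seq(1, ncol(d$sce), by = 8)]
  args <- list(sub, d$map, d$scn@hierarchy, epochs = 2L,
    batchSize = 32L, seed = 17L,
    config = classifierConfig(featureDim = 16L, f1 = 4L, f2 = 4L))
  m1 <- do.call(trainClassifier, args)
  m2 <- do.call(trainClassifier, args)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@trainLog, m2@trainLog)
  expect_identical(m1@stepLog, m2@stepLog)
})

test_that("the alpha trajectory is logged per step and stays in [0,1]", {
  m <- stdModel()
  expect_true(all(m@stepLog$alphaNext >= 0 & m@stepLog$alphaNext <= 1))
  expect_true(all(diff(m@stepLog$step) == 1L))
  expect_true(all(m@stepLog$flBase >= 0 & m@stepLog$flSub >= 0))
  # training log round-trips through the CSV writer
  f <- tempfile(fileext = ".csv")
  writeTrainLog(m, f)
  back <- read.csv(f)
  expect_equal(back$alpha, m@trainLog$alpha, tolerance = 1e-12)
})

test_that("the classifier recovers the planted populations on held-out
           cells", {
  d <- stdData()
  ev <- evaluateClassifier(stdModel(), d$sce[, d$test], d$map)
  expect_gte(ev$base$accuracy, 0.95)
  expect_gte(ev$subtype$accuracy, 0.90)
  # metrics agree with an independent recomputation from the dumped
  # confusion matrix
  conf <- ev$base$confusion
  expect_equal(ev$base$accuracy, sum(diag(conf)) / sum(conf),
    tolerance = 1e-12)
  prec <- diag(conf) / colSums(conf[, seq_len(nrow(conf))])
  expect_equal(ev$base$macroPrecision, mean(prec), tolerance = 1e-12)
  # the report writer serializes the same numbers
  pref <- tempfile()
  writeMetricsReport(ev, pref)
  js <- jsonlite::fromJSON(paste0(pref, ".metrics.json"))
  expect_equal(js$base$accuracy, ev$base$accuracy, tolerance = 1e-12)
  expect_true(file.exists(paste0(pref, ".confusion.base.tsv")))
})

test_that("adaptive weighting is not inferior to a fixed equal weight", {
  # matched short-budget arms: identical data, seed and settings, with the
  # alpha update the only difference
  d <- stdData()
  args <- list(d$sce[, d$train], d$map, d$scn@hierarchy,
    epochs = 40L, batchSize = 64L, lr = 3e-3, seed = 5L,
    maskFraction = 0.3, earlyStopPatience = 40L, config = stdConfig())
  adaptive <- do.call(trainClassifier, args)
  fixed <- do.call(trainClassifier, c(args, adaptiveAlpha = FALSE))
  evA <- evaluateClassifier(adaptive, d$sce[, d$test], d$map)
  evF <- evaluateClassifier(fixed, d$sce[, d$test], d$map)
  expect_gte(evA$subtype$accuracy, evF$subtype$accuracy - 0.02)
  # and the adaptive run's weight actually moved
  expect_gt(max(abs(adaptive@stepLog$alphaNext - 0.5)), 0.01)
})
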