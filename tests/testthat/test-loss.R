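test_that("focal loss matches closed-form values", {
  # perfectly classified example contributes nothing
  expect_equal(focalLoss(c(1, 0), 1L, gamma = 2), 0)
  expect_equal(focalLoss(c(1, 0), 1L, gamma = 0), 0)
  # gamma = 0: plain cross-entropy, -log(0.5)
  expect_equal(focalLoss(c(0.5, 0.5), 1L, gamma = 0), log(2),
    tolerance = 1e-12)
  # gamma = 2: (1-0.5)^2 * log 2 = 0.25 * 0.693147
  expect_equal(focalLoss(c(0.5, 0.5), 1L, gamma = 2), 0.25 * log(2),
    tolerance = 1e-12)
  # batch value is the mean over cells
  p <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  manual <- mean(c(-(1 - 0.9)^2 * log(0.9), -(1 - 0.8)^2 * log(0.8)))
  expect_equal(focalLoss(p, c(1L, 2L), gamma = 2), manual)
  expect_error(focalLoss(c(0.5, 0.5), 3L), "out of range")
})

test_that("gamma = 0 reduces focal loss to cross-entropy", {
  set.seed(1)
  for (i in 1:1000) {
    k <- sample(2:8, 1)
    p <- rexp(k); p <- p / sum(p)
    t <- sample(k, 1)
    expect_equal(focalLoss(p, t, gamma = 0), -log(p[t]),
      tolerance = 1e-9)
  }
})

test_that("total loss is the alpha-weighted convex combination", {
  expect_equal(totalLoss(2.5, 9, alpha = 1), 2.5)
  expect_equal(totalLoss(3, 3, alpha = 0.5), 3)
  expect_equal(totalLoss(1, 3, alpha = 0.475), 0.475 + 0.525 * 3)
  expect_error(totalLoss(1, 1, alpha = 1.2), "alpha")
})

test_that("alpha update follows the momentum-smoothed loss ratio", {
  st <- lossState(alpha = 0.5, beta = 0.9)
  # balanced losses: 0.5 is a fixed point
  expect_equal(updateAlpha(st, 2, 2)@alpha, 0.5)
  # worked example: 0.9*0.5 + 0.1 * 1/(1+3)
  expect_equal(updateAlpha(st, 1, 3)@alpha, 0.475, tolerance = 1e-12)
  # both levels perfect: ratio undefined, alpha unchanged
  expect_equal(updateAlpha(st, 0, 0)@alpha, 0.5)
  expect_equal(updateAlpha(st, 0, 0)@step, 1L)
  expect_error(updateAlpha(st, -1, 1), "non-negative")
})

test_that("alpha converges geometrically to a constant loss ratio", {
  st <- lossState(alpha = 0.5, beta = 0.9)
  r <- 1 / (1 + 3)
  gaps <- numeric(200)
  for (t in 1:200) {
    st <- updateAlpha(st, 1, 3)
    gaps[t] <- st@alpha - r
  }
  # closed form of the linear recurrence: gap_t = beta^t * (alpha0 - r)
  expect_equal(gaps, 0.9^(1:200) * (0.5 - r), tolerance = 1e-12)
})

test_that("alpha stays within [0,1] for arbitrary non-negative losses and
           responds monotonically to the base loss", {
  set.seed(2)
  st <- lossState(alpha = runif(1), beta = 0.9)
  for (i in 1:10000) {
    st <- updateAlpha(st, rexp(1, 1 / 5), rexp(1, 1 / 5))
    if (st@alpha < 0 || st@alpha > 1) fail("alpha left [0,1]")
  }
  succeed()
  # directionality: larger FL_base -> larger next alpha, FL_sub fixed
  base <- lossState(alpha = 0.5)
  a1 <- updateAlpha(base, 1, 2)@alpha
  a2 <- updateAlpha(base, 1.5, 2)@alpha
  a3 <- updateAlpha(base, 3, 2)@alpha
  expect_true(a1 < a2 && a2 < a3)
})

test_that("hierarchical loss step excludes unlabeled-subtype cells and
           defers the alpha update to the next step", {
  h <- tinyHier()
  st <- lossState(alpha = 0.5, gamma = 2)
  # one-cell batch, p_true = 0.5 at both levels: both FLs 0.25*log 2
  out <- hierarchicalLossStep(matrix(c(0.5, 0.5), 1),
    matrix(c(0.5, 0.5), 1), list(base = 1L, sub = 1L), st)
  expect_equal(out$loss, 0.25 * log(2), tolerance = 1e-12)
  expect_equal(out$flBase, out$flSub)
  # loss computed with alpha_t = 0.5; the state then moved to the ratio
  expect_equal(out$state@alpha, 0.5)

  # all-terminal batch: subtype loss skipped, alpha untouched
  bp <- rbind(c(0.3, 0.7), c(0.4, 0.6))
  sp <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  out2 <- hierarchicalLossStep(bp, sp, list(base = c(2L, 2L),
    sub = c(NA_integer_, NA_integer_)), st)
  expect_equal(out2$flSub, 0)
  expect_equal(out2$loss, 0.5 * out2$flBase)
  expect_equal(out2$state@alpha, 0.5)
  expect_equal(out2$state@step, 1L)

  # perfect predictions: zero loss, alpha unchanged
  out3 <- hierarchicalLossStep(matrix(c(1, 0), 1), matrix(c(1, 0), 1),
    list(base = 1L, sub = 1L), st)
  expect_equal(out3$loss, 0)
  expect_equal(out3$state@alpha, 0.5)
})

test_that("analytic loss gradients w.r.t. logits match finite differences", {
  set.seed(3)
  n <- 4L; kb <- 3L; ks <- 5L
  zb <- matrix(rnorm(n * kb), n); zs <- matrix(rnorm(n * ks), n)
  enc <- list(base = c(1L, 2L, 3L, 1L), sub = c(2L, NA, 4L, 5L))
  st <- lossState(alpha = 0.4, gamma = 2)
  lossOf <- function(zb, zs) {
    pb <- exp(zb) / rowSums(exp(zb))
    ps <- exp(zs) / rowSums(exp(zs))
    hierarchicalLossStep(pb, ps, enc, st)$loss
  }
  pb <- exp(zb) / rowSums(exp(zb))
  ps <- exp(zs) / rowSums(exp(zs))
  gb <- st@alpha * scImageHier:::.focalGradLogits(pb, enc$base, st@gamma)
  gs <- (1 - st@alpha) * scImageHier:::.focalGradLogits(ps, enc$sub,
    st@gamma)
  eps <- 1e-6
  for (i in seq_along(zb)) {
    z2 <- zb; z2[i] <- z2[i] + eps; up <- lossOf(z2, zs)
    z2[i] <- z2[i] - 2 * eps; dn <- lossOf(z2, zs)
    expect_equal(gb[i], (up - dn) / (2 * eps), tolerance = 1e-4)
  }
  for (i in seq_along(zs)) {
    z2 <- zs; z2[i] <- z2[i] + eps; up <- lossOf(zb, z2)
    z2[i] <- z2[i] - 2 * eps; dn <- lossOf(zb, z2)
    expect_equal(gs[i], (up - dn) / (2 * eps), tolerance = 1e-4)
  }
})
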