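# Compact convolutional backbone ("tiny_cnn") in plain matrix algebra.
#
# Two 3x3 conv blocks (ReLU) with 2x2 max-pooling, followed by a dense
# feature layer and two linear heads (base types, subtypes). On small grids
# (<= 32) only the second block is pooled, preserving per-pixel (per-gene)
# resolution where single pixels carry the signal; larger grids pool after
# both blocks to bound the dense layer. Activations are held as (H*W, n, C)
# arrays so convolutions reduce to one im2col matrix product per layer;
# backprop is analytic and is verified against finite differences in the
# test suite.
#
# Weight layout for a conv layer: (9*Cin) x Cout, rows ordered channel-major
# then offset (dr, dc) row-major within a channel. The heavy kernels
# (conv gather/GEMM/scatter, pooling) are compiled (src/conv.cpp).

# ---- geometry helpers (precomputed once per layer) ----

.convGeom <- function(h, w) {
  hp <- h + 2L; wp <- w + 2L
  r <- rep(seq_len(h), w); cc <- rep(seq_len(w), each = h)
  padPos <- cc * hp + r + 1L                  # (r, c) -> padded (r+1, c+1)
  nbr <- matrix(0L, h * w, 9L)
  j <- 0L
  for (dc in 0:2) for (dr in 0:2) {           # offset-major order
    j <- j + 1L
    nbr[, j] <- (cc + dc - 1L) * hp + (r + dr)
  }
  list(h = h, w = w, hp = hp, wp = wp, padPos = padPos, nbr = nbr)
}

.poolGeom <- function(h, w) {
  h2 <- h %/% 2L; w2 <- w %/% 2L
  r2 <- rep(seq_len(h2), w2); c2 <- rep(seq_len(w2), each = h2)
  at <- function(dr, dc) ((2L * c2 - 1L + dc) - 1L) * h + (2L * r2 - 1L + dr)
  list(h2 = h2, w2 = w2,
    idx = cbind(at(0L, 0L), at(1L, 0L), at(0L, 1L), at(1L, 1L)))
}

# ---- layers ----
# thin wrappers over the compiled kernels in src/conv.cpp

.convForward <- function(A, W, b, geom) {
  list(out = .convForwardCpp(A, W, b, geom$nbr, geom$padPos,
    geom$hp * geom$wp))
}

# A is the layer's input activation (needed to recompute the gathers)
.convBackward <- function(A, dOut, W, geom, needInput = TRUE) {
  .convBackwardCpp(A, dOut, W, geom$nbr, geom$padPos,
    geom$hp * geom$wp, needInput)
}

.poolForward <- function(A, pg) {
  .poolForwardCpp(A, pg$idx)
}

.poolBackward <- function(dOut, argmax, pg, hwIn) {
  .poolBackwardCpp(dOut, argmax, pg$idx, hwIn)
}

# ---- parameter initialization ----

.initTinyCnn <- function(h, w, featureDim, kBase, kSub, f1 = 8L, f2 = 16L,
    seed = 1L, pool1 = NULL) {
  # small grids keep full resolution through both conv blocks (one pool at
  # the end); larger grids pool after each block to bound the dense layer
  if (is.null(pool1)) pool1 <- min(h, w) > 32L
  div <- if (pool1) 4L else 2L
  if (h %% div != 0L || w %% div != 0L)
    stop("tiny_cnn needs image height and width divisible by ", div,
      " (got ", h, " x ", w, ")")
  set.seed(seed)
  he <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  flat <- (h %/% div) * (w %/% div) * f2
  params <- list(
    Wc1 = he(9L, f1),            bc1 = rep(0, f1),
    Wc2 = he(9L * f1, f2),       bc2 = rep(0, f2),
    Wd  = he(flat, featureDim),  bd  = rep(0, featureDim),
    Wb  = he(featureDim, kBase), bb  = rep(0, kBase),
    Ws  = if (kSub > 0) he(featureDim, kSub) else matrix(0, featureDim, 0),
    bs  = rep(0, max(kSub, 0)))
  attr(params, "arch") <- list(h = h, w = w, f1 = f1, f2 = f2,
    featureDim = featureDim, kBase = kBase, kSub = kSub, pool1 = pool1)
  params
}

# ---- full forward / backward ----

# stack: n x H x W array -> logits and cache
.tinyForward <- function(stack, params, dropProb = NULL) {
  arch <- attr(params, "arch")
  n <- dim(stack)[1L]
  h <- arch$h; w <- arch$w
  g1 <- .convGeom(h, w)
  if (arch$pool1) {
    p1 <- .poolGeom(h, w)
    h1 <- p1$h2; w1 <- p1$w2
  } else {
    p1 <- NULL
    h1 <- h; w1 <- w
  }
  g2 <- .convGeom(h1, w1); p2 <- .poolGeom(h1, w1)

  A0 <- array(aperm(stack, c(2, 3, 1)), c(h * w, n, 1L))
  c1 <- .convForward(A0, params$Wc1, params$bc1, g1)
  r1 <- pmax(c1$out, 0)
  q1 <- if (arch$pool1) .poolForward(r1, p1) else list(out = r1)
  c2 <- .convForward(q1$out, params$Wc2, params$bc2, g2)
  r2 <- pmax(c2$out, 0)
  q2 <- .poolForward(r2, p2)
  q2$out <- array(q2$out, dim(q2$out))
  # flatten: per-cell feature = (pixels x channels), cells as rows
  flat <- t(matrix(aperm(q2$out, c(1, 3, 2)), ncol = n))
  zd <- sweep(flat %*% params$Wd, 2L, params$bd, "+")
  feat <- pmax(zd, 0)
  # inverted dropout on the feature layer (training only)
  dropMask <- NULL
  if (!is.null(dropProb) && dropProb > 0) {
    dropMask <- matrix(rbinom(length(feat), 1L, 1 - dropProb),
      nrow(feat)) / (1 - dropProb)
    feat <- feat * dropMask
  }
  zb <- sweep(feat %*% params$Wb, 2L, params$bb, "+")
  zs <- if (arch$kSub > 0)
    sweep(feat %*% params$Ws, 2L, params$bs, "+")
    else matrix(0, n, 0L)
  list(baseLogits = zb, subLogits = zs,
    cache = list(n = n, g1 = g1, p1 = p1, h1 = h1, w1 = w1, g2 = g2,
      p2 = p2, A0 = A0,
      c1 = c1, r1 = r1, q1 = q1, c2 = c2, r2 = r2, q2 = q2,
      flat = flat, zd = zd, feat = feat, dropMask = dropMask))
}

# dZb, dZs: gradients of the scalar loss w.r.t. the two heads' logits
.tinyBackward <- function(dZb, dZs, params, cache, needInput = FALSE) {
  arch <- attr(params, "arch")
  n <- cache$n
  grads <- list()
  grads$Wb <- crossprod(cache$feat, dZb); grads$bb <- colSums(dZb)
  dFeat <- dZb %*% t(params$Wb)
  if (arch$kSub > 0 && length(dZs)) {
    grads$Ws <- crossprod(cache$feat, dZs); grads$bs <- colSums(dZs)
    dFeat <- dFeat + dZs %*% t(params$Ws)
  } else {
    grads$Ws <- matrix(0, arch$featureDim, arch$kSub)
    grads$bs <- rep(0, arch$kSub)
  }
  if (!is.null(cache$dropMask)) dFeat <- dFeat * cache$dropMask
  dZd <- dFeat * (cache$zd > 0)
  grads$Wd <- crossprod(cache$flat, dZd); grads$bd <- colSums(dZd)
  dFlat <- dZd %*% t(params$Wd)
  # unflatten back to (pixels, n, channels)
  hw2 <- cache$p2$h2 * cache$p2$w2
  dQ2 <- aperm(array(t(dFlat), c(hw2, arch$f2, n)), c(1, 3, 2))
  dR2 <- .poolBackward(dQ2, cache$q2$argmax, cache$p2,
    cache$h1 * cache$w1)
  dC2 <- dR2 * (cache$c2$out > 0)
  b2 <- .convBackward(cache$q1$out, dC2, params$Wc2, cache$g2, TRUE)
  grads$Wc2 <- b2$dW; grads$bc2 <- b2$db
  dR1 <- if (arch$pool1)
    .poolBackward(b2$dA, cache$q1$argmax, cache$p1, arch$h * arch$w)
    else b2$dA
  dC1 <- dR1 * (cache$c1$out > 0)
  b1 <- .convBackward(cache$A0, dC1, params$Wc1, cache$g1, needInput)
  grads$Wc1 <- b1$dW; grads$bc1 <- b1$db
  dInput <- NULL
  if (needInput)
    dInput <- aperm(array(b1$dA, c(arch$h, arch$w, n)), c(3, 1, 2))
  list(grads = grads, dInput = dInput)
}

.softmaxRows <- function(z) {
  if (ncol(z) == 0L) return(z)
  z <- z - matrixStats::rowMaxs(z)
  e <- exp(z)
  e / rowSums(e)
}

# ---- Adam ----

.adamInit <- function(params) {
  nm <- setdiff(names(params), character(0))
  list(t = 0L,
    m = lapply(params[nm], function(p) p * 0),
    v = lapply(params[nm], function(p) p * 0))
}

# Adam with decoupled weight decay on the weight matrices (biases exempt)
.adamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
    eps = 1e-8, weightDecay = 0) {
  opt$t <- opt$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (!length(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    step <- lr * mhat / (sqrt(vhat) + eps)
    if (weightDecay > 0 && startsWith(nm, "W"))
      step <- step + lr * weightDecay * params[[nm]]
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, opt = opt)
}
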