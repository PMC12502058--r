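#' Construct a loss state
#'
#' @param alpha initial adaptive weight (default 0.5: equal emphasis on the
#'   two levels, and the update's fixed point when the per-level losses are
#'   balanced).
#' @param beta momentum of the alpha update (default 0.9).
#' @param gamma focal focusing parameter (default 2).
#' @return a [LossState-class].
#' @export
lossState <- function(alpha = 0.5, beta = 0.9, gamma = 2.0) {
  new("LossState", alpha = alpha, beta = beta, gamma = gamma,
    lastFlBase = 0, lastFlSub = 0, step = 0L)
}

#' Focal loss
#'
#' `FL(p) = -(1 - p_true)^gamma * log(p_true)`: cross-entropy down-weighted
#' for well-classified examples, so that training gradient concentrates on
#' hard (typically rare-class) cells. With `gamma = 0` it reduces exactly to
#' cross-entropy. For a matrix of per-cell probability vectors the batch
#' value is the mean over cells.
#'
#' @param probs probability vector on the simplex, or a cells x classes
#'   matrix of such vectors.
#' @param trueClass 1-based true class index (scalar, or vector per cell).
#' @param gamma focusing parameter, >= 0.
#' @return non-negative scalar loss.
#' @export
focalLoss <- function(probs, trueClass, gamma = 2.0) {
  if (is.matrix(probs)) {
    if (length(trueClass) != nrow(probs))
      stop("one true class per row required")
    if (any(trueClass < 1L | trueClass > ncol(probs)))
      stop("class index out of range")
    pt <- probs[cbind(seq_len(nrow(probs)), trueClass)]
  } else {
    if (trueClass < 1L || trueClass > length(probs))
      stop("class index out of range")
    pt <- probs[trueClass]
  }
  pt <- pmin(pmax(pt, 1e-12), 1)
  mean(-(1 - pt)^gamma * log(pt))
}

#' Two-level total loss
#'
#' Convex combination of the base-level and subtype-level focal losses:
#' `L_total = alpha * flBase + (1 - alpha) * flSub`.
#'
#' @param flBase,flSub per-level focal losses.
#' @param alpha weight in \[0,1\].
#' @return the combined loss.
#' @export
totalLoss <- function(flBase, flSub, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0,1]")
  alpha * flBase + (1 - alpha) * flSub
}

#' Momentum-smoothed adaptive weight update
#'
#' `alpha_{t+1} = beta * alpha_t + (1 - beta) * flBase / (flBase + flSub)`.
#' The loss ratio is the adaptation signal: when the base level trains
#' easily (low `flBase`) the weight drifts toward the subtype level, and
#' vice versa; `beta` smooths the drift. If both losses are zero the ratio
#' is undefined and alpha is left unchanged.
#'
#' @param state a [LossState-class].
#' @param flBase,flSub the step's focal losses (non-negative).
#' @return the updated [LossState-class] (step incremented, losses recorded).
#' @export
updateAlpha <- function(state, flBase, flSub) {
  if (flBase < 0 || flSub < 0) stop("losses must be non-negative")
  alpha <- if (flBase + flSub == 0) state@alpha
    else state@beta * state@alpha +
      (1 - state@beta) * flBase / (flBase + flSub)
  methods::initialize(state, alpha = alpha, lastFlBase = flBase,
    lastFlSub = flSub, step = state@step + 1L)
}

#' One training-step loss evaluation
#'
#' Computes the base-level focal loss over all cells and the subtype-level
#' focal loss over the cells that carry a subtype label (cells of terminal
#' lineages, whose subtype index is `NA`, are excluded; if no cell in the
#' batch has one, `flSub = 0` and alpha is not updated). Returns the total
#' loss computed with the *current* alpha, then applies the alpha update so
#' the new weight takes effect next step.
#'
#' @param baseProbs cells x nBase probability matrix.
#' @param subProbs cells x nSub probability matrix (raw, unmasked — the
#'   subtype head trains over all subtypes).
#' @param enc encoded labels from [encodeLabels()].
#' @param state a [LossState-class].
#' @return list with `loss` (total), `flBase`, `flSub`, and `state` (the
#'   updated [LossState-class]).
#' @export
hierarchicalLossStep <- function(baseProbs, subProbs, enc, state) {
  flBase <- focalLoss(baseProbs, enc$base, state@gamma)
  withSub <- which(!is.na(enc$sub))
  flSub <- if (length(withSub))
    focalLoss(subProbs[withSub, , drop = FALSE], enc$sub[withSub],
      state@gamma) else 0
  loss <- totalLoss(flBase, flSub, state@alpha)
  newState <- if (length(withSub)) updateAlpha(state, flBase, flSub)
    else methods::initialize(state, lastFlBase = flBase, lastFlSub = 0,
      step = state@step + 1L)
  list(loss = loss, flBase = flBase, flSub = flSub, state = newState)
}

# gradient of the batch-mean focal loss w.r.t. logits, given softmax probs;
# returns a cells x classes matrix (rows for cells with NA class are zero)
.focalGradLogits <- function(probs, trueClass, gamma) {
  n <- nrow(probs)
  g <- matrix(0, n, ncol(probs))
  ok <- which(!is.na(trueClass))
  if (!length(ok)) return(g)
  for (i in ok) {
    p <- probs[i, ]
    t <- trueClass[i]
    u <- min(max(p[t], 1e-12), 1)
    # dFL/du, with FL = -(1-u)^g log u
    dldu <- if (gamma == 0) -1 / u
      else gamma * (1 - u)^(gamma - 1) * log(u) - (1 - u)^gamma / u
    # du/dz_j = u (delta_jt - p_j)
    dz <- dldu * u * (-p)
    dz[t] <- dz[t] + dldu * u
    g[i, ] <- dz
  }
  g / length(ok)   # batch mean over contributing cells
}

setMethod("show", "LossState", function(object) {
  cat(sprintf(
    "LossState: alpha = %.4f (beta = %.2f, gamma = %.1f), step %d\n",
    object@alpha, object@beta, object@gamma, object@step))
  if (object@step > 0)
    cat(sprintf("  last FL_base = %.5f, FL_sub = %.5f\n",
      object@lastFlBase, object@lastFlSub))
})
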