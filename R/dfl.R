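# Distribution focal loss: each continuous box offset is modelled as a
# discrete probability distribution over reg_max + 1 integer bins; the loss is
# the cross-entropy against the two bins bracketing the target, weighted by
# linear interpolation. The expectation over bins decodes back to the offset.

#' Discrete bin distribution for distribution focal loss
#'
#' @param probs Nonnegative weight vector of length `reg_max + 1` summing to 1
#'   (within 1e-6); bin `i` corresponds to offset value `i - 1` (zero-based).
#' @param reg_max Number of bins minus one; the default 16 gives 17 bins.
#' @return An object of class `bin_distribution`.
#' @export
bin_distribution <- function(probs, reg_max = 16L) {
  stopifnot(is.numeric(probs), all(is.finite(probs)))
  reg_max <- as.integer(reg_max)
  if (reg_max < 1L) stop("'reg_max' must be >= 1")
  if (length(probs) != reg_max + 1L) {
    stop(sprintf("'probs' must have length reg_max + 1 = %d (got %d)",
                 reg_max + 1L, length(probs)))
  }
  if (any(probs < 0)) stop("'probs' must be nonnegative")
  if (abs(sum(probs) - 1) > 1e-6) {
    stop(sprintf("'probs' must sum to 1 within 1e-6 (sum = %.8f)", sum(probs)))
  }
  structure(list(probs = as.numeric(probs), reg_max = reg_max),
            class = "bin_distribution")
}

#' @export
print.bin_distribution <- function(x, ...) {
  cat(sprintf("<bin_distribution> reg_max %d, expectation %.4f\n",
              x$reg_max, decode_expectation(x)))
  invisible(x)
}

#' Bracketing-bin target for distribution focal loss
#'
#' Splits a continuous regression target `y` (in bin units, i.e. already
#' divided by the detector's bin width) into its bracketing integer bins
#' `yi = floor(y)` and `yi1 = yi + 1` with linear-interpolation weights
#' `(yi1 - y, y - yi)`. At the upper end `y = reg_max` the pair is clamped to
#' `(reg_max - 1, reg_max)` so both bins stay in range.
#'
#' @param y Continuous target in `[0, reg_max]`.
#' @param reg_max Bin count parameter (default 16).
#' @return A list of class `dfl_target` with fields `y`, `yi`, `yi1`,
#'   `weights` (the two interpolation weights) and `reg_max`.
#' @export
dfl_target <- function(y, reg_max = 16L) {
  stopifnot(is.numeric(y), length(y) == 1L, is.finite(y))
  reg_max <- as.integer(reg_max)
  if (y < 0 || y > reg_max) {
    stop(sprintf(
      "regression target y = %.6g outside [0, %d]; targets must be scaled to bin units",
      y, reg_max))
  }
  yi <- min(floor(y), reg_max - 1L)
  yi1 <- yi + 1L
  structure(
    list(y = as.numeric(y), yi = as.integer(yi), yi1 = as.integer(yi1),
         weights = c(yi1 - y, y - yi), reg_max = reg_max),
    class = "dfl_target"
  )
}

#' Distribution focal loss
#'
#' Cross-entropy of the predicted bin distribution against the two-hot target:
#' `-( (yi1 - y) * log(S[yi]) + (y - yi) * log(S[yi1]) )`, where `S[i]` is the
#' predicted probability of bin `i`. Probabilities at the needed bins are
#' clamped below by `eps` before the logarithm. The loss is minimized, over
#' all distributions, by placing the linear-interpolation weights on the two
#' bracketing bins, in which case the decoded expectation recovers `y` exactly.
#'
#' @param dist A [bin_distribution()].
#' @param target A [dfl_target()] with the same `reg_max`.
#' @param eps Log clamp for zero-probability bins (default 1e-12).
#' @return Nonnegative loss value.
#' @examples
#' d <- bin_distribution(c(rep(0, 3), 0.3, 0.7, rep(0, 12)), 16)
#' dfl_loss(d, dfl_target(3.7, 16)) # -(0.3 log 0.3 + 0.7 log 0.7)
#' @export
dfl_loss <- function(dist, target, eps = 1e-12) {
  stopifnot(inherits(dist, "bin_distribution"), inherits(target, "dfl_target"))
  if (dist$reg_max != target$reg_max) {
    stop("distribution and target use different 'reg_max'")
  }
  s_lo <- max(dist$probs[target$yi + 1L], eps)  # probs is zero-based in bins
  s_hi <- max(dist$probs[target$yi1 + 1L], eps)
  -(target$weights[1] * log(s_lo) + target$weights[2] * log(s_hi))
}

#' Ideal two-hot distribution for a target
#'
#' The distribution minimizing [dfl_loss()] for a given target: all mass on
#' the two bracketing bins with the linear-interpolation weights.
#'
#' @param target A [dfl_target()].
#' @return A [bin_distribution()].
#' @export
dfl_ideal_distribution <- function(target) {
  stopifnot(inherits(target, "dfl_target"))
  p <- numeric(target$reg_max + 1L)
  p[target$yi + 1L] <- target$weights[1]
  p[target$yi1 + 1L] <- target$weights[2]
  bin_distribution(p, target$reg_max)
}

#' Decode a bin distribution to its expected offset
#'
#' `sum(i * S[i])` over zero-based bins `i = 0, ..., reg_max`; the standard
#' decoding that turns a predicted distribution back into a continuous box
#' offset in bin units.
#'
#' @param dist A [bin_distribution()].
#' @return Expected value in `[0, reg_max]`.
#' @export
decode_expectation <- function(dist) {
  stopifnot(inherits(dist, "bin_distribution"))
  sum((seq_along(dist$probs) - 1) * dist$probs)
}

#' Combined rotated-box regression loss
#'
#' Weighted sum of the ProbIoU and distribution focal components:
#' `l_total = 0.8 * l_prob + 0.2 * l_dfl` with the default weights. The
#' detection task is single-class with regression only, so this is the whole
#' training loss.
#'
#' @param l_prob ProbIoU loss in `[0, 1]`.
#' @param l_dfl Distribution focal loss, `>= 0`.
#' @param weights Length-2 weights for the two components.
#' @return A list of class `loss_breakdown` with `l_prob`, `l_dfl`, `l_total`.
#' @examples
#' total_loss(1, 0)$l_total # 0.8
#' @export
total_loss <- function(l_prob, l_dfl, weights = c(prob = 0.8, dfl = 0.2)) {
  stopifnot(is.numeric(l_prob), is.numeric(l_dfl), length(weights) == 2L)
  if (l_prob < 0 || l_prob > 1) stop("'l_prob' must lie in [0, 1]")
  if (l_dfl < 0) stop("'l_dfl' must be >= 0")
  structure(
    list(l_prob = as.numeric(l_prob), l_dfl = as.numeric(l_dfl),
         l_total = as.numeric(weights[[1]] * l_prob + weights[[2]] * l_dfl),
         weights = unname(as.numeric(weights))),
    class = "loss_breakdown"
  )
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss_breakdown> l_prob %.6g  l_dfl %.6g  ->  l_total %.6g (weights %.2g/%.2g)\n",
              x$l_prob, x$l_dfl, x$l_total, x$weights[1], x$weights[2]))
  invisible(x)
}
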