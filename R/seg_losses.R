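# Reference implementations of the segmentation losses used to train the
# mask-producing networks upstream of this pipeline.  Pure numeric, no
# gradients: they exist for unit-level verification and spot checks.

CLIP_EPS <- 1e-12

#' Multi-class cross-entropy loss
#'
#' Mean over elements of `-sum_i y_i log p_i`, with probabilities clipped to
#' `[1e-12, 1]` before the log so a zero true-class probability yields a
#' large finite value rather than infinity.
#'
#' @param p Numeric matrix (n x classes) of predicted probabilities, or a
#'   vector for a single element.
#' @param y One-hot matrix (or vector) of true labels, same shape as `p`.
#' @return Non-negative scalar.
#' @export
cross_entropy <- function(p, y) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  if (!identical(dim(p), dim(y))) stop("shape mismatch between p and y")
  if (any(p < -1e-9) || any(p > 1 + 1e-9)) stop("probabilities must lie in [0, 1]")
  pc <- pmin(pmax(p, CLIP_EPS), 1)
  mean(rowSums(-y * log(pc)))
}

#' Focal loss for a scalar true-class probability
#'
#' `-alpha_t * (1 - p_t)^gamma * log(p_t)`. At `gamma = 0` this reduces to a
#' weighted cross-entropy; as `p_t -> 1` it vanishes.  `gamma` is the
#' focusing (moderating) exponent, default 2.
#'
#' @param p_t True-class probability (vectorised), clipped like
#'   [cross_entropy()].
#' @param alpha_t Non-negative class weight.
#' @param gamma Non-negative focusing exponent.
#' @return Non-negative value(s), same length as `p_t`.
#' @export
focal_loss <- function(p_t, alpha_t = 1, gamma = 2) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (alpha_t < 0) stop("alpha_t must be >= 0")
  pc <- pmin(pmax(p_t, CLIP_EPS), 1)
  -alpha_t * (1 - pc)^gamma * log(pc)
}

#' Dice coefficient of two binary arrays
#'
#' `(2|X ∩ Y| + eps) / (|X| + |Y| + eps)` with the intersection taken as the
#' elementwise-product sum.  The Dice loss is `1 - dice_coefficient`.
#'
#' @param X,Y Binary arrays of congruent shape.
#' @param epsilon Positive smoothing term.
#' @return Scalar in (0, 1].
#' @export
dice_coefficient <- function(X, Y, epsilon = 1e-6) {
  if (length(X) != length(Y)) stop("shape mismatch between X and Y")
  if (epsilon <= 0) stop("epsilon must be > 0")
  x <- as.numeric(X); y <- as.numeric(Y)
  (2 * sum(x * y) + epsilon) / (sum(x) + sum(y) + epsilon)
}

#' Dice loss (complement of the Dice coefficient)
#' @inheritParams dice_coefficient
#' @return Scalar in `[0, 1)`.
#' @export
dice_loss <- function(X, Y, epsilon = 1e-6) 1 - dice_coefficient(X, Y, epsilon)

#' Generalized Dice loss from confusion counts
#'
#' `1 - ((1 + d^2) TP + eps) / ((1 + d^2) TP + d^2 FN + FP + eps)` with
#' `d = delta` trading precision against recall.  At `delta = 1` this equals
#' `1 - (2 TP + eps) / (2 TP + FN + FP + eps)`, i.e. one minus the Dice
#' coefficient of sets with `|X| = TP + FN`, `|Y| = TP + FP`.
#'
#' @param TP,FP,FN,TN Non-negative confusion counts (`TN` unused, accepted
#'   for completeness).
#' @param delta Non-negative trade-off parameter.
#' @param epsilon Positive smoothing term.
#' @return Scalar in [0, 1].
#' @export
dice_loss_generalized <- function(TP, FP, FN, TN = 0, delta = 1, epsilon = 1e-6) {
  if (any(c(TP, FP, FN, TN) < 0)) stop("confusion counts must be >= 0")
  if (delta < 0) stop("delta must be >= 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  d2 <- delta^2
  1 - ((1 + d2) * TP + epsilon) / ((1 + d2) * TP + d2 * FN + FP + epsilon)
}

#' Evaluate losses from a JSON record (CLI helper)
#'
#' The record may contain `{"p": [...], "y": [...]}` (cross-entropy),
#' `{"p_t":, "alpha_t":, "gamma":}` (focal), `{"X": [...], "Y": [...]}`
#' (Dice) and/or `{"TP":, "FP":, "FN":, "delta":, "epsilon":}` (generalized
#' Dice).
#'
#' @param record A list (e.g. from `jsonlite::read_json`).
#' @return Named list of computed loss values.
#' @export
eval_losses_record <- function(record) {
  out <- list()
  if (!is.null(record$p) && !is.null(record$y))
    out$cross_entropy <- cross_entropy(do.call(rbind, lapply(record$p, unlist)),
                                       do.call(rbind, lapply(record$y, unlist)))
  if (!is.null(record$p_t))
    out$focal_loss <- focal_loss(unlist(record$p_t),
                                 record$alpha_t %||% 1, record$gamma %||% 2)
  if (!is.null(record$X) && !is.null(record$Y))
    out$dice_coefficient <- dice_coefficient(unlist(record$X), unlist(record$Y),
                                             record$epsilon %||% 1e-6)
  if (!is.null(record$TP))
    out$dice_loss_generalized <- dice_loss_generalized(
      record$TP, record$FP %||% 0, record$FN %||% 0, record$TN %||% 0,
      record$delta %||% 1, record$epsilon %||% 1e-6)
  out
}
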