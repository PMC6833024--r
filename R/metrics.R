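#' Soft Dice loss between a probability map and a binary mask
#'
#' Computes \eqn{1 - 2\sum_{ij} P_{ij} G_{ij} / (\sum_{ij} P_{ij}^2 +
#' \sum_{ij} G_{ij}^2)}, the Dice-coefficient loss used to train the
#' segmentation networks.  `P` may be real-valued (training) or binary
#' (evaluation); no thresholding is applied internally.
#'
#' @param P numeric matrix with entries in `[0, 1]` (predicted probabilities).
#' @param G binary matrix (0/1 ground truth) of the same dimensions.
#' @return A single number in `[0, 1]`; 0 iff `P` is binary and equal to a
#'   non-empty `G`.
#' @examples
#' G <- matrix(c(1, 0, 0, 1), 2, 2)
#' dice_loss(matrix(0.5, 2, 2), G)  # 1/3
#' @export
dice_loss <- function(P, G) {
  stopifnot(is.matrix(P) || is.array(P), is.matrix(G) || is.array(G))
  if (!all(dim(P) == dim(G)))
    stop("dice_loss: P and G must have identical dimensions")
  check_prob_grid(P)
  check_binary_mask(G)
  denom <- sum(P^2) + sum(G^2)
  if (denom == 0)
    stop("dice_loss: P and G are both identically zero (0/0)")
  1 - 2 * sum(P * G) / denom
}

# gradient of dice_loss wrt P (used by the trainers)
dice_loss_grad <- function(P, G) {
  s_pg <- sum(P * G)
  denom <- sum(P^2) + sum(G^2)
  -(2 * G * denom - 4 * s_pg * P) / denom^2
}

#' Pixel-level confusion counts between two binary masks
#'
#' @param pred,G binary matrices (0/1) of identical dimensions; `pred` is the
#'   prediction, `G` the ground truth.
#' @return A list of class `confusion_counts` with integer fields
#'   `tp`, `fp`, `fn`, `tn` summing to the number of pixels.
#' @export
confusion_counts <- function(pred, G) {
  if (!all(dim(pred) == dim(G)))
    stop("confusion_counts: masks must have identical dimensions")
  check_binary_mask(pred)
  check_binary_mask(G)
  p <- pred == 1
  g <- G == 1
  structure(list(tp = sum(p & g), fp = sum(p & !g),
                 fn = sum(!p & g), tn = sum(!p & !g)),
            class = "confusion_counts")
}

#' Segmentation scores from confusion counts
#'
#' Precision, recall, F-score (`2 P R / (P + R)`), IoU, sensitivity and
#' specificity.  Degenerate 0/0 cases resolve by convention: with no positive
#' predictions, precision is 1 when nothing was missed and 0 otherwise; two
#' empty masks score F = IoU = 1 (vacuous success); specificity is 1 when
#' there are no true negatives or false positives.
#'
#' @param counts a `confusion_counts` object (or list with tp/fp/fn/tn).
#' @return A list of class `segmentation_scores` with fields `precision`,
#'   `recall`, `f_score`, `iou`, `sensitivity`, `specificity`, all in `[0, 1]`.
#' @export
scores_from_counts <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  precision <- if (tp + fp == 0) (if (fn == 0) 1 else 0) else tp / (tp + fp)
  recall    <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f_score   <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  iou       <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  specificity <- if (tn + fp == 0) 1 else tn / (tn + fp)
  structure(list(precision = precision, recall = recall, f_score = f_score,
                 iou = iou, sensitivity = recall, specificity = specificity),
            class = "segmentation_scores")
}

#' F-score and friends directly from two binary masks
#' @inheritParams confusion_counts
#' @return see [scores_from_counts()]
#' @export
mask_scores <- function(pred, G) scores_from_counts(confusion_counts(pred, G))

#' ROC area under the curve via the rank (Mann-Whitney) statistic
#'
#' AUC equals the probability that a randomly chosen positive outscores a
#' randomly chosen negative, ties counted one half.  Computed exactly from
#' ranks, not by trapezoidal curve integration.
#'
#' @param scores numeric vector of classifier scores.
#' @param labels 0/1 vector of the same length; at least one of each class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("roc_auc: need at least one positive and one negative label")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# ---- internal validation helpers ------------------------------------------

check_prob_grid <- function(P) {
  if (any(P < 0 | P > 1)) stop("probability grid has values outside [0, 1]")
  invisible(P)
}

check_binary_mask <- function(G) {
  if (!all(G %in% c(0, 1))) stop("mask has values other than 0/1")
  invisible(G)
}

#' @export
print.segmentation_scores <- function(x, ...) {
  cat(sprintf(
    "segmentation scores: F = %.4f  IoU = %.4f  sens = %.4f  spec = %.4f\n",
    x$f_score, x$iou, x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d FP=%d FN=%d TN=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}
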