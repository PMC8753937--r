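#' F1 score of a (soft) prediction against a binary gold mask
#'
#' The prediction is binarized at `threshold`; F1 = 2TP / (2TP + FP + FN)
#' over the foreground class. When both maps are empty the score is 1;
#' when the denominator is zero but gold has foreground it is 0.
#'
#' @param pred prediction map (soft or binary matrix)
#' @param gold binary reference mask
#' @param threshold binarization threshold for `pred` (default 0.5)
#' @return F1 in `[0, 1]`
#' @export
f1_score <- function(pred, gold, threshold = 0.5) {
  check_same_shape(pred, gold, "pred/gold")
  check_binary_mask(gold, "gold")
  p <- pred >= threshold
  g <- gold > 0
  tp <- sum(p & g)
  denom <- 2 * tp + sum(p & !g) + sum(!p & g)
  if (denom == 0) return(1)
  2 * tp / denom
}

#' Area under the precision--recall curve (average precision)
#'
#' Pixels are ranked by score; the curve is traced over all distinct
#' score thresholds (ties grouped) and integrated by the step-wise
#' average-precision rule `sum (R_k - R_{k-1}) * P_k` -- not the
#' trapezoid, which is optimistic on PR curves. Invariant under strictly
#' monotone transforms of the scores; a constant classifier scores the
#' foreground prevalence.
#'
#' @param pred score map (matrix); soft values are used directly
#' @param gold binary reference mask with at least one foreground and one
#'   background pixel
#' @return area in `[0, 1]`
#' @export
pr_auc <- function(pred, gold) {
  check_same_shape(pred, gold, "pred/gold")
  check_binary_mask(gold, "gold")
  n_pos <- sum(gold)
  if (n_pos == 0 || n_pos == length(gold))
    stop("gold must contain both foreground and background pixels",
         call. = FALSE)
  o <- order(pred, decreasing = TRUE)
  g <- gold[o]
  s <- pred[o]
  tp <- cumsum(g)
  fp <- cumsum(1 - g)
  # keep the last index of each tied score group
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate a set of maps against gold masks
#'
#' Computes per-image F1 (binarized at `threshold`) and PR area, then
#' macro-averages across images (each image weighs equally, regardless of
#' its foreground size); the averaging convention is recorded in the
#' output.
#'
#' @param preds named list of prediction matrices
#' @param golds named list of binary gold matrices (same names)
#' @param threshold F1 binarization threshold
#' @return list with `per_image` (data.frame: id, f1, pr_auc, n_pixels)
#'   and `macro` (named numeric: f1, pr_auc), plus `threshold` and
#'   `averaging = "macro"`
#' @export
evaluate_maps <- function(preds, golds, threshold = 0.5) {
  ids <- names(preds)
  if (is.null(ids) || !setequal(ids, names(golds)))
    stop("preds and golds must be named lists over the same image ids",
         call. = FALSE)
  per <- do.call(rbind, lapply(ids, function(id) {
    data.frame(id = id,
               f1 = f1_score(preds[[id]], golds[[id]], threshold),
               pr_auc = pr_auc(preds[[id]], golds[[id]]),
               n_pixels = length(golds[[id]]))
  }))
  list(per_image = per,
       macro = c(f1 = mean(per$f1), pr_auc = mean(per$pr_auc)),
       threshold = threshold, averaging = "macro")
}
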