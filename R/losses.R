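#' Loss configuration
#'
#' @param lambda_weight weight of the noisy-label term in the temporal
#'   memory loss; the framework's preset is 0.1
#' @param clamp_eps probabilities are clamped to `[clamp_eps, 1 - clamp_eps]`
#'   before taking logs
#' @return a `loss_config` list
#' @export
loss_config <- function(lambda_weight = 0.1, clamp_eps = 1e-7) {
  if (lambda_weight < 0) stop_param("lambda_weight", "must be >= 0")
  if (clamp_eps <= 0 || clamp_eps >= 0.5)
    stop_param("clamp_eps", "must be in (0, 0.5)")
  structure(list(lambda_weight = lambda_weight, clamp_eps = clamp_eps,
                 reduction = "mean"), class = "loss_config")
}

#' Binary cross-entropy with soft targets
#'
#' Mean over pixels of `-(t log s + (1 - t) log(1 - s))`. Targets may be
#' continuous: corrected label maps and historical-best predictions are
#' soft, and the criterion is applied to them directly without
#' binarization.
#'
#' @param pred probability map (matrix)
#' @param target map in `[0, 1]`, same shape
#' @param cfg a [loss_config()]
#' @return scalar loss
#' @export
bce <- function(pred, target, cfg = loss_config()) {
  check_same_shape(pred, target, "pred/target")
  s <- pmin(pmax(pred, cfg$clamp_eps), 1 - cfg$clamp_eps)
  -mean(target * log(s) + (1 - target) * log(1 - s))
}

# analytic gradient of bce w.r.t. pred (used only for gradient checks;
# training backprop differentiates w.r.t. the sigmoid pre-activation)
bce_grad <- function(pred, target, cfg = loss_config()) {
  check_same_shape(pred, target, "pred/target")
  s <- pmin(pmax(pred, cfg$clamp_eps), 1 - cfg$clamp_eps)
  g <- (-target / s + (1 - target) / (1 - s)) / length(pred)
  g[pred < cfg$clamp_eps | pred > 1 - cfg$clamp_eps] <- 0
  g
}

#' Temporal memory loss
#'
#' `E(S, S_best) + lambda * E(S, L)`: the prediction is self-supervised by
#' the cycle's historical best prediction and weakly supervised by the
#' current (possibly noisy) label map. The historical best is a constant
#' target; no gradient flows back into the memory bank.
#'
#' @param pred current prediction map S
#' @param best historical best prediction from the memory bank
#' @param label current supervision map L^j
#' @param cfg a [loss_config()]
#' @return scalar loss
#' @export
temporal_memory_loss <- function(pred, best, label, cfg = loss_config()) {
  if (is.null(best))
    stop("memory bank not yet populated; use warmup_loss()", call. = FALSE)
  check_same_shape(pred, best, "pred/best")
  check_same_shape(pred, label, "pred/label")
  bce(pred, best, cfg) + cfg$lambda_weight * bce(pred, label, cfg)
}

#' Warm-up loss
#'
#' Plain `E(S, L)` -- the label term of the temporal memory loss without
#' the weight, used during initialization and for the first `T` epochs of
#' each cycle while the memory bank accumulates.
#'
#' @inheritParams temporal_memory_loss
#' @return scalar loss
#' @export
warmup_loss <- function(pred, label, cfg = loss_config()) bce(pred, label, cfg)
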