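#' Label state for one image
#'
#' Holds the frozen initial noisy mask `L^0` and the current corrected
#' soft map `L^j`. Cycle 1 trains on `L^0` itself; the first correction
#' happens at the end of cycle 1.
#'
#' @param initial the initial noisy label map (matrix in `[0, 1]`)
#' @return a `label_state` list with fields `initial`, `current`,
#'   `cycle_index`
#' @export
label_state <- function(initial) {
  if (!is.matrix(initial) || any(initial < 0 | initial > 1))
    stop_param("initial", "must be a matrix with values in [0, 1]")
  structure(list(initial = initial, current = initial, cycle_index = 0L),
            class = "label_state")
}

#' Per-pixel confidence map from the memory bank
#'
#' `d = |best - worst|` is the rangeability of the cycle's historical
#' predictions at each pixel. A LARGE value means the prediction swung
#' widely during the cycle, i.e. the pixel is unstable and its final
#' prediction is NOT to be trusted; a small value means a stable,
#' confident prediction.
#'
#' @param best historical best prediction map
#' @param worst historical worst prediction map
#' @return matrix `D` in `[0, 1]`
#' @export
confidence_map <- function(best, worst) {
  check_same_shape(best, worst, "best/worst")
  abs(best - worst)
}

#' Label-correction compensation
#'
#' `Q = D * best + (1 - D) * final_pred`, element-wise: where history was
#' unstable (large D) the compensation leans on the historical best, which
#' is more stable than the last-epoch prediction; where the prediction was
#' stable it trusts the final prediction.
#'
#' @param D confidence map in `[0, 1]` from [confidence_map()]
#' @param best historical best prediction map
#' @param final_pred last-epoch prediction map of the cycle
#' @return matrix `Q`, element-wise between `min(best, final_pred)` and
#'   `max(best, final_pred)`
#' @export
compensation <- function(D, best, final_pred) {
  check_same_shape(D, best, "D/best")
  check_same_shape(D, final_pred, "D/final_pred")
  if (any(D < 0 | D > 1))
    stop_param("D", "must lie in [0, 1]")
  D * best + (1 - D) * final_pred
}

#' Cycle-end label update
#'
#' `L^{j+1} = 1/(j+1) * L^0 + j/(j+1) * Q^j` for cycle `j >= 1`: a convex
#' combination anchored at the initial labels, with the compensation's
#' weight growing as training progresses. Inputs in `[0, 1]` stay in
#' `[0, 1]` by convexity; a clamp guards float error only.
#'
#' @param state a [label_state()]
#' @param Q compensation map from [compensation()]
#' @param j cycle index, `>= 1` (cycle 1 trains on `L^0` directly, so no
#'   update precedes it)
#' @return the updated `label_state` with `current = L^{j+1}` and
#'   `cycle_index = j + 1`
#' @export
update_labels <- function(state, Q, j) {
  if (!inherits(state, "label_state")) stop_param("state", "not a label_state")
  if (j < 1) stop("label update is defined for cycle index j >= 1", call. = FALSE)
  check_same_shape(state$initial, Q, "initial/Q")
  if (any(Q < 0 | Q > 1)) stop_param("Q", "must lie in [0, 1]")
  upd <- state$initial / (j + 1) + Q * j / (j + 1)
  state$current <- pmin(pmax(upd, 0), 1)
  state$cycle_index <- as.integer(j + 1)
  state
}

#' Write corrected label maps to disk
#'
#' Each map is exported both as a soft 8-bit grayscale PNG (values scaled
#' to 0--255) and as a binarized PNG at threshold 0.5, with filenames
#' suffixed `_cycle{j}`.
#'
#' @param labels named list of label matrices in `[0, 1]`
#' @param dir output directory (created if missing)
#' @param cycle cycle index used in the filename suffix
#' @return invisibly, the written file paths
#' @export
write_labels_png <- function(labels, dir, cycle) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(labels)) {
    L <- labels[[nm]]
    soft <- file.path(dir, sprintf("%s_soft_cycle%d.png", nm, cycle))
    hard <- file.path(dir, sprintf("%s_bin_cycle%d.png", nm, cycle))
    png::writePNG(L, soft)
    png::writePNG((L >= 0.5) * 1, hard)
    paths <- c(paths, soft, hard)
  }
  invisible(paths)
}
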