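#' Per-pixel temporal memory bank
#'
#' For every training image the bank keeps, per pixel, the historical best
#' prediction of the current cycle (the recorded value closest to the
#' cycle's supervision map `L^j`) and the historical worst (farthest).
#' Because `L^j` is fixed within a cycle, incremental strict-inequality
#' replacement is exactly the argmin / argmax over all recorded epochs,
#' while storing only two maps and their deviations per image (O(1) in the
#' number of epochs). Ties keep the earliest recorded value.
#'
#' Predictions must be recorded in canonical (un-augmented) orientation;
#' each augmented view is reversed and recorded as a separate update.
#'
#' @return a `memory_bank` object
#' @export
memory_bank <- function() {
  structure(list(store = new.env(parent = emptyenv())), class = "memory_bank")
}

#' Reset a memory bank for a new cycle
#'
#' The argmin/argmax of the bank run over the epochs of one cycle only;
#' mixing cycles would compare predictions against a stale supervision
#' map, so the trainer resets the bank at every cycle start.
#'
#' @param bank a [memory_bank()]
#' @param image_ids ignored; entries auto-initialize on first update
#' @return the bank, invisibly
#' @export
bank_reset <- function(bank, image_ids = NULL) {
  rm(list = ls(bank$store), envir = bank$store)
  invisible(bank)
}

#' Record one prediction into the bank
#'
#' Element-wise, the best map is replaced wherever the new prediction is
#' strictly closer to the supervision map than the stored best, and the
#' worst wherever it is strictly farther.
#'
#' @param bank a [memory_bank()]
#' @param image_id character or integer image key
#' @param prediction probability map in canonical orientation
#' @param label the cycle's supervision map `L^j` (fixed within a cycle;
#'   the bank checks this by checksum and errors if it changes mid-cycle)
#' @return the bank, invisibly
#' @export
bank_update <- function(bank, image_id, prediction, label) {
  check_same_shape(prediction, label, "prediction/label")
  key <- as.character(image_id)
  dev <- abs(prediction - label)
  dg <- digest::digest(label)
  e <- bank$store[[key]]
  if (is.null(e)) {
    bank$store[[key]] <- list(best = prediction, worst = prediction,
                              best_dev = dev, worst_dev = dev,
                              n_updates = 1L, label_digest = dg)
    return(invisible(bank))
  }
  if (!identical(e$label_digest, dg))
    stop("supervision map changed mid-cycle; reset the bank at cycle start",
         call. = FALSE)
  better <- dev < e$best_dev
  worse <- dev > e$worst_dev
  e$best[better] <- prediction[better]
  e$best_dev[better] <- dev[better]
  e$worst[worse] <- prediction[worse]
  e$worst_dev[worse] <- dev[worse]
  e$n_updates <- e$n_updates + 1L
  bank$store[[key]] <- e
  invisible(bank)
}

bank_entry <- function(bank, image_id) {
  e <- bank$store[[as.character(image_id)]]
  if (is.null(e))
    stop(sprintf("memory bank not yet populated for image '%s'", image_id),
         call. = FALSE)
  e
}

#' Historical best / worst prediction maps
#'
#' @param bank a [memory_bank()]
#' @param image_id image key
#' @return a matrix (a defensive copy; R value semantics guarantee the
#'   bank's copy cannot be modified through it)
#' @export
bank_best <- function(bank, image_id) bank_entry(bank, image_id)$best

#' @rdname bank_best
#' @export
bank_worst <- function(bank, image_id) bank_entry(bank, image_id)$worst

#' @rdname bank_best
#' @export
bank_is_populated <- function(bank, image_id) {
  !is.null(bank$store[[as.character(image_id)]])
}

#' Number of updates recorded for one image this cycle
#' @inheritParams bank_best
#' @export
bank_n_updates <- function(bank, image_id) bank_entry(bank, image_id)$n_updates

#' Total updates recorded across all images this cycle
#' @param bank a [memory_bank()]
#' @export
bank_total_updates <- function(bank) {
  ids <- ls(bank$store)
  if (length(ids) == 0) return(0L)
  sum(vapply(ids, function(k) bank$store[[k]]$n_updates, integer(1)))
}
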