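#' Write a dataset to a directory
#'
#' Layout: `images/*.png` (8-bit grayscale), `gold/*.png` and
#' `noisy/*.png` (binary masks, foreground = 255), plus `manifest.json`
#' recording ids and generation metadata.
#'
#' @param data list of [sample_record()]s
#' @param dir output directory
#' @param meta optional list stored in the manifest (e.g. the noise spec)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(data, dir, meta = NULL) {
  for (sub in c("images", "gold", "noisy"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  ids <- character(length(data))
  for (i in seq_along(data)) {
    rec <- data[[i]]
    ids[i] <- rec$id
    png::writePNG(rec$image, file.path(dir, "images", paste0(rec$id, ".png")))
    png::writePNG(sample_gold(rec), file.path(dir, "gold", paste0(rec$id, ".png")))
    png::writePNG(rec$noisy, file.path(dir, "noisy", paste0(rec$id, ".png")))
  }
  jsonlite::write_json(list(ids = ids, meta = meta),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' Also accepts DRIVE/STARE/CHASE-style layouts reduced to the same three
#' folders. Masks are binarized at 0.5 on read.
#'
#' @param dir dataset directory
#' @return list of [sample_record()]s
#' @export
read_dataset <- function(dir) {
  manifest <- file.path(dir, "manifest.json")
  ids <- if (file.exists(manifest)) {
    unlist(jsonlite::read_json(manifest)$ids)
  } else {
    sub("\\.png$", "", list.files(file.path(dir, "images"), pattern = "\\.png$"))
  }
  read_gray <- function(path) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- a[, , 1]
    a
  }
  lapply(ids, function(id) {
    img <- read_gray(file.path(dir, "images", paste0(id, ".png")))
    gold_path <- file.path(dir, "gold", paste0(id, ".png"))
    gold <- if (file.exists(gold_path)) (read_gray(gold_path) >= 0.5) * 1 else NULL
    noisy <- (read_gray(file.path(dir, "noisy", paste0(id, ".png"))) >= 0.5) * 1
    sample_record(id, img, gold, noisy)
  })
}
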