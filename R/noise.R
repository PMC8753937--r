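#' Label-noise specification
#'
#' Three pollution mechanisms at three severity levels. `contour_approx`
#' replaces each component's traced contour with a polygonal
#' approximation (the synthetic-noise mechanism of the framework);
#' `dilation_erosion` and `dropout` are cheap labeled surrogates for
#' annotator-style thickening/thinning and pseudo-label component loss --
#' they do not reproduce any published noise model.
#'
#' Level-to-tolerance defaults are LV1 = 1.5, LV2 = 3 and LV3 = 6 px,
#' interpreted as absolute pixels: the phantoms' vessels have the same
#' absolute thickness as vessels in standard fundus images at native
#' resolution, so the tolerance does not scale with image size. Supply
#' `scale_ref` to scale `eps` by `size / scale_ref` when your structures
#' do scale with the image.
#'
#' @param kind one of `"contour_approx"`, `"dilation_erosion"`, `"dropout"`
#' @param level one of `"LV1"`, `"LV2"`, `"LV3"`
#' @param seed integer seed for the stochastic mechanisms
#' @param scale_ref optional reference image side for eps scaling
#' @return a `noise_spec` list with the resolved `eps`
#' @export
noise_spec <- function(kind = c("contour_approx", "dilation_erosion", "dropout"),
                       level = c("LV1", "LV2", "LV3"), seed = 0,
                       scale_ref = NULL) {
  kind <- match.arg(kind)
  level <- match.arg(level)
  eps <- c(LV1 = 1.5, LV2 = 3, LV3 = 6)[[level]]
  structure(list(kind = kind, level = level, eps = eps, seed = seed,
                 scale_ref = scale_ref), class = "noise_spec")
}

resolve_eps <- function(spec, size) {
  if (is.null(spec$scale_ref)) spec$eps else spec$eps * size / spec$scale_ref
}

#' Corrupt a mask by polygonal contour approximation
#'
#' Emulates rough manual annotation: the closed contour of every
#' 8-connected foreground component (outer boundary plus hole
#' boundaries) is traced, simplified Douglas-Peucker-style at tolerance
#' `eps`, and refilled (even-odd scanline, boundary pixels inclusive).
#' Components whose simplified polygon degenerates below 3 vertices are
#' deleted outright, realizing pixel-label deletion; surviving
#' components get shifted and straightened contours.
#'
#' @param mask binary matrix
#' @param eps approximation tolerance in pixels, `>= 0`
#' @param seed kept for interface symmetry; the operator is deterministic
#' @return binary matrix of the same shape
#' @export
corrupt_contour_approx <- function(mask, eps, seed = 0) {
  check_binary_mask(mask)
  if (!is.numeric(eps) || eps < 0) stop_param("eps", "must be >= 0")
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0, H, W)

  lab <- label_components(mask, conn = 8)
  ncomp <- max(lab)
  if (ncomp == 0) return(out)
  for (k in seq_len(ncomp)) {
    fg <- lab == k
    if (sum(fg) == 1) {
      if (eps == 0) out[fg] <- 1  # single pixel survives only untouched
      next
    }
    contour <- trace_contour(fg)
    poly <- dp_simplify_closed(contour, eps)
    poly <- drop_consecutive_dups(poly)
    if (nrow(unique(poly)) < 3) {  # degenerate: component deleted (unless lossless)
      if (eps == 0) out[fg] <- 1
      next
    }
    out <- pmax(out, fill_polygon(poly, H, W))
  }

  # holes: interior background components, traced and re-approximated
  bg <- label_components(1 - mask, conn = 4)
  border_ids <- unique(c(bg[1, ], bg[H, ], bg[, 1], bg[, W]))
  hole_ids <- setdiff(unique(bg[bg > 0]), border_ids)
  for (k in hole_ids) {
    hole <- bg == k
    if (sum(hole) <= 2) next  # tiny holes are absorbed
    poly <- drop_consecutive_dups(dp_simplify_closed(trace_contour(hole), eps))
    if (nrow(unique(poly)) < 3) next
    out[fill_polygon(poly, H, W, draw_boundary = TRUE) == 1] <- 0
  }
  out
}

#' Surrogate noise: per-component morphological thickening/thinning
#'
#' Each component is randomly dilated or eroded by a disk whose radius
#' grows with `eps`. A labeled surrogate for inter-annotator
#' thickness disagreement.
#'
#' @inheritParams corrupt_contour_approx
#' @export
corrupt_dilation_erosion <- function(mask, eps, seed = 0) {
  check_binary_mask(mask)
  with_seed(seed, {
    lab <- label_components(mask, conn = 8)
    out <- matrix(0, nrow(mask), ncol(mask))
    r <- max(1L, as.integer(round(eps / 2)))
    for (k in seq_len(max(lab))) {
      comp <- (lab == k) * 1
      comp <- if (runif(1) < 0.5) morph_disk(comp, r, dilate = TRUE)
              else morph_disk(comp, r, dilate = FALSE)
      out <- pmax(out, comp)
    }
    out
  })
}

#' Surrogate noise: random component dropout
#'
#' Deletes whole components at random, small ones preferentially; the
#' deletion probability grows with `eps`. A labeled surrogate for
#' pseudo-label misses.
#'
#' @inheritParams corrupt_contour_approx
#' @export
corrupt_dropout <- function(mask, eps, seed = 0) {
  check_binary_mask(mask)
  with_seed(seed, {
    lab <- label_components(mask, conn = 8)
    out <- mask
    p0 <- min(0.9, eps / 8)
    for (k in seq_len(max(lab))) {
      sz <- sum(lab == k)
      if (runif(1) < p0 * exp(-sz / 400)) out[lab == k] <- 0
    }
    out
  })
}

morph_disk <- function(m, r, dilate = TRUE) {
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r^2, ]
  H <- nrow(m); W <- ncol(m)
  acc <- if (dilate) matrix(0, H, W) else matrix(1, H, W)
  for (i in seq_len(nrow(offs))) {
    ri <- pmin(pmax(seq_len(H) + offs$dr[i], 1), H)
    ci <- pmin(pmax(seq_len(W) + offs$dc[i], 1), W)
    sh <- m[ri, ci, drop = FALSE]
    acc <- if (dilate) pmax(acc, sh) else pmin(acc, sh)
  }
  acc
}

apply_noise <- function(mask, spec, seed) {
  eps <- resolve_eps(spec, nrow(mask))
  switch(spec$kind,
         contour_approx = corrupt_contour_approx(mask, eps, seed),
         dilation_erosion = corrupt_dilation_erosion(mask, eps, seed),
         dropout = corrupt_dropout(mask, eps, seed))
}

#' One training sample
#'
#' Bundles an image with its initial noisy mask `L^0` and -- for
#' evaluation only -- the gold mask. The gold mask is reachable solely
#' through [sample_gold()], which refuses access while training code
#' holds the gold lock, so no training-path code can peek at it.
#'
#' @param id character id
#' @param image image matrix in `[0, 1]`
#' @param gold binary gold mask (evaluation only)
#' @param noisy binary initial noisy mask `L^0`
#' @return a `sample_record`
#' @export
sample_record <- function(id, image, gold, noisy) {
  structure(list(id = as.character(id), image = image,
                 gold_sealed = gold, noisy = noisy),
            class = "sample_record")
}

#' Read a record's gold mask (evaluation only)
#'
#' Errors if called while the training-path gold lock is held (the
#' trainer sets it for the duration of every training epoch).
#'
#' @param rec a [sample_record()]
#' @return the gold mask matrix
#' @export
sample_gold <- function(rec) {
  if (isTRUE(getOption("vesselmend.gold_locked", FALSE)))
    stop("gold masks are locked: training-path code must not read them",
         call. = FALSE)
  rec$gold_sealed
}

#' Generate a noisy synthetic dataset
#'
#' `n` vessel phantoms, each with `L^0` obtained by corrupting the gold
#' mask with the given noise specification. Fully deterministic under
#' (`n`, `noise`, `seed`).
#'
#' @param n number of samples, `>= 1`
#' @param noise a [noise_spec()]
#' @param seed integer master seed
#' @param size,n_trees,thickness forwarded to [generate_phantom()]
#' @return list of [sample_record()]s
#' @export
make_noisy_dataset <- function(n, noise = noise_spec(), seed = 0,
                               size = 128, n_trees = 3, thickness = c(1, 3.5)) {
  if (!is.numeric(n) || n < 1) stop_param("n", "must be >= 1")
  lapply(seq_len(n), function(i) {
    ph_seed <- (as.numeric(seed) * 7919 + i * 104729) %% 2147483629
    ph <- generate_phantom(ph_seed, size = size, n_trees = n_trees,
                           thickness = thickness)
    noisy <- apply_noise(ph$gold_mask, noise,
                         seed = (noise$seed * 6007 + i) %% 2147483629)
    sample_record(sprintf("img%03d", i), ph$image, ph$gold_mask, noisy)
  })
}
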