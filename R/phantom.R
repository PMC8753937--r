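#' Generate a synthetic vessel phantom
#'
#' A stand-in for a retinal fundus image with its expert annotation: the
#' gold mask is the union of smooth random curvilinear strokes ("trees",
#' each a jittered random walk with 1--2 thinner branches) with thickness
#' tapering toward the tip; the image is a blurred, inverted copy of the
#' mask (dark vessels on a bright background) plus a low-frequency
#' background field and Gaussian pixel noise, rescaled to `[0, 1]`.
#' Identical seed and parameters give bit-identical output, and the
#' caller's RNG stream is left untouched.
#'
#' @param seed integer seed
#' @param size image side in pixels (square), `>= 32`
#' @param n_trees number of vessel trees, `>= 1`
#' @param thickness length-2 numeric: min and max stroke thickness in px
#' @return a `vessel_phantom` list: `image` (matrix in `[0, 1]`),
#'   `gold_mask` (binary matrix), `meta` (generator parameters)
#' @export
generate_phantom <- function(seed, size = 128, n_trees = 3,
                             thickness = c(1, 3.5)) {
  if (!is.numeric(size) || size < 32) stop_param("size", "must be >= 32")
  if (!is.numeric(n_trees) || n_trees < 1) stop_param("n_trees", "must be >= 1")
  if (length(thickness) != 2 || any(thickness <= 0) ||
      thickness[1] > thickness[2])
    stop_param("thickness", "must be an increasing positive range")
  size <- as.integer(size)

  out <- with_seed(seed, {
    mask <- matrix(0, size, size)
    for (t in seq_len(n_trees)) {
      edge <- sample(4, 1)
      pos <- runif(1, 0.15, 0.85) * size
      start <- switch(edge,
                      c(2, pos), c(size - 1, pos), c(pos, 2), c(pos, size - 1))
      ang0 <- switch(edge, pi / 2, -pi / 2, 0, pi) + rnorm(1, 0, 0.4)
      main <- draw_stroke(mask, start, ang0,
                          len = round(size * runif(1, 0.9, 1.3)),
                          th0 = runif(1, 0.75, 1) * thickness[2],
                          th1 = thickness[1])
      mask <- main$mask
      path <- main$path
      for (b in seq_len(1 + rbinom(1, 1, 0.6))) {
        at <- sample(seq(5, max(6, nrow(path) - 5)), 1)
        bang <- main$angles[at] + sample(c(-1, 1), 1) * runif(1, 0.5, 1.1)
        bth <- max(thickness[1], main$ths[at] * 0.7)
        mask <- draw_stroke(mask, path[at, ], bang,
                            len = round(size * runif(1, 0.35, 0.6)),
                            th0 = bth, th1 = thickness[1])$mask
      }
    }
    bg <- outer(seq_len(size), seq_len(size), function(r, c)
      0.5 + 0.5 * sin(2 * pi * r / size + runif(1) * 6) *
        cos(2 * pi * c / size + runif(1) * 6))
    img <- 0.85 - 0.55 * gauss_blur(mask, sigma = 1) +
      0.08 * bg + matrix(rnorm(size^2, 0, 0.04), size, size)
    img <- (img - min(img)) / (max(img) - min(img))
    list(image = img, gold_mask = mask)
  })
  structure(list(image = out$image, gold_mask = out$gold_mask,
                 meta = list(seed = seed, size = size, n_trees = n_trees,
                             thickness = thickness)),
            class = "vessel_phantom")
}

# one tapering curvilinear stroke; returns updated mask + path/angles/ths
draw_stroke <- function(mask, start, ang, len, th0, th1) {
  size <- nrow(mask)
  r <- start[1]; c <- start[2]
  path <- matrix(NA_real_, len, 2)
  angles <- ths <- numeric(len)
  n <- 0
  for (i in seq_len(len)) {
    if (r < 1 || r > size || c < 1 || c > size) break
    n <- i
    th <- th0 + (th1 - th0) * (i - 1) / max(1, len - 1)
    path[i, ] <- c(r, c)
    angles[i] <- ang
    ths[i] <- th
    mask <- stamp_disk(mask, r, c, th / 2)
    ang <- ang + rnorm(1, 0, 0.12)
    r <- r + sin(ang)
    c <- c + cos(ang)
  }
  list(mask = mask, path = path[seq_len(n), , drop = FALSE],
       angles = angles[seq_len(n)], ths = ths[seq_len(n)])
}

stamp_disk <- function(mask, r, c, radius) {
  size <- nrow(mask)
  rr <- max(0.5, radius)
  i0 <- max(1, floor(r - rr)); i1 <- min(size, ceiling(r + rr))
  j0 <- max(1, floor(c - rr)); j1 <- min(size, ceiling(c + rr))
  for (i in i0:i1)
    for (j in j0:j1)
      if ((i - r)^2 + (j - c)^2 <= rr^2) mask[i, j] <- 1
  mask
}

# separable Gaussian blur with replicated edges
gauss_blur <- function(m, sigma = 1) {
  half <- max(1, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(x) {
    n <- nrow(x)
    out <- matrix(0, n, ncol(x))
    for (d in -half:half) {
      idx <- pmin(pmax(seq_len(n) + d, 1), n)
      out <- out + k[d + half + 1] * x[idx, , drop = FALSE]
    }
    out
  }
  t(smooth1(t(smooth1(m))))
}
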