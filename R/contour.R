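# Raster geometry helpers for the contour-approximation noise operator:
# connected-component labeling, Moore boundary tracing, Douglas-Peucker
# polyline simplification, scanline polygon fill and Bresenham lines.
# Coordinates are (row, col), 1-based internally.

# label connected components; conn = 8 (foreground) or 4 (background)
label_components <- function(m, conn = 8) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  if (conn == 8) {
    offs <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    offs <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  todo <- which(m != 0)
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      pr <- ((p - 1L) %% H) + 1L
      pc <- ((p - 1L) %/% H) + 1L
      nr <- pr + offs[, 1]; nc <- pc + offs[, 2]
      ok <- nr >= 1 & nr <= H & nc >= 1 & nc <= W
      idx <- (nc[ok] - 1L) * H + nr[ok]
      idx <- idx[m[idx] != 0 & lab[idx] == 0L]
      if (length(idx)) {
        lab[idx] <- cur
        queue <- c(queue, idx)
      }
    }
  }
  lab
}

# Moore-neighbor boundary tracing with Jacob's stopping criterion.
# fg: logical matrix for one component. Returns an n x 2 matrix of the
# closed boundary (may repeat pixels on 1-px-wide structures).
trace_contour <- function(fg) {
  H <- nrow(fg); W <- ncol(fg)
  # clockwise neighbourhood starting North
  dr <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
  start_idx <- which(fg)[1]
  sr <- ((start_idx - 1L) %% H) + 1L
  sc <- ((start_idx - 1L) %/% H) + 1L
  # entered from the West (raster scan guarantees W neighbour is bg)
  at <- function(r, c) r >= 1 && r <= H && c >= 1 && c <= W && fg[r, c]
  pts <- matrix(c(sr, sc), 1, 2)
  cr <- sr; cc <- sc
  back <- 7L  # direction index (1-based) of the backtrack: West
  first_dir <- NA_integer_
  max_iter <- 4L * (H * W + 4L)
  for (iter in seq_len(max_iter)) {
    found <- FALSE
    for (k in seq_len(8)) {
      d <- ((back - 1L + k - 1L) %% 8L) + 1L  # scan clockwise from backtrack
      nr <- cr + dr[d]; nc <- cc + dc[d]
      if (at(nr, nc)) {
        if (cr == sr && cc == sc) {
          if (is.na(first_dir)) first_dir <- d
          else if (d == first_dir && iter > 1L) return(pts[-nrow(pts), , drop = FALSE])
        }
        # new backtrack: the neighbour just before d, relative to the new pixel
        prev <- ((d - 2L) %% 8L) + 1L
        pr <- cr + dr[prev]; pc <- cc + dc[prev]
        back <- which(dr == pr - nr & dc == pc - nc)
        cr <- nr; cc <- nc
        pts <- rbind(pts, c(cr, cc))
        found <- TRUE
        break
      }
    }
    if (!found) return(pts)  # isolated pixel
    if (cr == sr && cc == sc && nrow(pts) > 1L) {
      # will confirm via first_dir on next scan; also hard stop if tiny loop
      if (nrow(pts) > 4L * sum(fg) + 8L) return(pts[-nrow(pts), , drop = FALSE])
    }
  }
  pts
}

# perpendicular distance of points to the segment (a, b)
seg_dist <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((pts[, 1] - (a[1] + t * ab[1]))^2 + (pts[, 2] - (a[2] + t * ab[2]))^2)
}

# Douglas-Peucker simplification of an open polyline; keeps endpoints
dp_simplify <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2) return(pts)
  keep <- logical(n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    rg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rg[1]; j <- rg[2]
    if (j - i < 2) next
    mid <- (i + 1):(j - 1)
    d <- seg_dist(pts[mid, , drop = FALSE], pts[i, ], pts[j, ])
    kmax <- which.max(d)
    if (d[kmax] > eps) {
      k <- mid[kmax]
      keep[k] <- TRUE
      stack <- c(stack, list(c(i, k), c(k, j)))
    }
  }
  pts[keep, , drop = FALSE]
}

# simplify a closed contour: split at the two mutually farthest anchor
# points, simplify each chain, and rejoin
dp_simplify_closed <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 3) return(pts)
  d0 <- (pts[, 1] - pts[1, 1])^2 + (pts[, 2] - pts[1, 2])^2
  k <- which.max(d0)
  if (k <= 2) return(dp_simplify(pts, eps))
  c1 <- dp_simplify(pts[1:k, , drop = FALSE], eps)
  c2 <- dp_simplify(rbind(pts[k:n, , drop = FALSE], pts[1, ]), eps)
  out <- rbind(c1, c2[-1, , drop = FALSE])
  if (all(out[nrow(out), ] == out[1, ])) out <- out[-nrow(out), , drop = FALSE]
  out
}

# remove consecutive duplicate vertices (also across the closing edge)
drop_consecutive_dups <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(pts)
  keep <- c(TRUE, rowSums(abs(pts[-1, , drop = FALSE] -
                              pts[-n, , drop = FALSE])) > 0)
  pts <- pts[keep, , drop = FALSE]
  n <- nrow(pts)
  if (n > 1 && all(pts[n, ] == pts[1, ])) pts <- pts[-n, , drop = FALSE]
  pts
}

bresenham <- function(a, b) {
  x0 <- a[1]; y0 <- a[2]; x1 <- b[1]; y1 <- b[2]
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- sign(x1 - x0); sy <- sign(y1 - y0)
  err <- dx - dy
  out <- matrix(NA_real_, dx + dy + 1, 2)
  i <- 0
  repeat {
    i <- i + 1
    out[i, ] <- c(x0, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2 * err
    if (e2 > -dy) { err <- err - dy; x0 <- x0 + sx }
    if (e2 < dx) { err <- err + dx; y0 <- y0 + sy }
  }
  out[seq_len(i), , drop = FALSE]
}

# rasterize a polygon (vertices n x 2, closed implicitly): nonzero-winding
# scanline fill plus boundary-inclusive edge drawing. The winding rule is
# deliberate: traced contours of thin strokes run out and back over the
# same pixels, and those coincident opposite edges must cancel instead of
# flipping parity.
fill_polygon <- function(poly, H, W, draw_boundary = TRUE) {
  out <- matrix(0, H, W)
  m <- nrow(poly)
  if (m < 3) return(out)
  nxt <- c(2:m, 1)
  r0 <- poly[, 1]; c0 <- poly[, 2]
  r1 <- poly[nxt, 1]; c1 <- poly[nxt, 2]
  rmin <- max(1, floor(min(r0))); rmax <- min(H, ceiling(max(r0)))
  for (r in rmin:rmax) {
    down <- r0 <= r & r1 > r
    up <- r1 <= r & r0 > r
    crosses <- down | up
    if (!any(crosses)) next
    xs <- c0[crosses] + (r - r0[crosses]) *
      (c1[crosses] - c0[crosses]) / (r1[crosses] - r0[crosses])
    sgn <- ifelse(down[crosses], 1L, -1L)
    o <- order(xs)
    xs <- xs[o]
    wind <- cumsum(sgn[o])
    for (p in seq_len(length(xs) - 1)) {
      if (wind[p] == 0) next
      j0 <- max(1, ceiling(xs[p])); j1 <- min(W, floor(xs[p + 1]))
      if (j0 <= j1) out[r, j0:j1] <- 1
    }
  }
  if (draw_boundary) {
    for (e in seq_len(m)) {
      seg <- bresenham(poly[e, ], poly[nxt[e], ])
      ok <- seg[, 1] >= 1 & seg[, 1] <= H & seg[, 2] >= 1 & seg[, 2] <= W
      out[seg[ok, , drop = FALSE]] <- 1
    }
  }
  out
}
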