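#' Small U-Net-style segmenter
#'
#' A depth-4 encoder--decoder with 3x3 convolutions, ReLU activations,
#' 2x2 max-pooling, nearest-neighbour upsampling with skip concatenation,
#' and a 1x1 convolution + sigmoid head producing a per-pixel foreground
#' probability. The width (channels of the first encoder level) is
#' configurable down to 8 so that CPU training at desk scale is feasible;
#' deeper levels use 2x, 4x and 8x the base width. Forward and backward
#' passes are written out explicitly (no autodiff framework is used);
#' convolution and pooling primitives are compiled.
#'
#' @param width channels of the first encoder level (default 8)
#' @param in_ch input channels (1 for grayscale)
#' @param seed optional integer seed for weight initialization
#' @return an opaque parameter list accepted by [unet_predict()]
#' @export
unet_init <- function(width = 8, in_ch = 1, seed = NULL) {
  if (width < 1) stop_param("width", "must be >= 1")
  w <- as.integer(width)
  init_conv <- function(cin, cout, k = 3) {
    fan_in <- k * k * cin
    list(W = matrix(rnorm(k * k * cin * cout) * sqrt(2 / fan_in),
                    k * k * cin, cout),
         b = rep(0, cout))
  }
  build <- function() {
    list(
      enc1a = init_conv(in_ch, w),     enc1b = init_conv(w, w),
      enc2a = init_conv(w, 2 * w),     enc2b = init_conv(2 * w, 2 * w),
      enc3a = init_conv(2 * w, 4 * w), enc3b = init_conv(4 * w, 4 * w),
      bota  = init_conv(4 * w, 8 * w), botb  = init_conv(8 * w, 8 * w),
      dec3a = init_conv(12 * w, 4 * w), dec3b = init_conv(4 * w, 4 * w),
      dec2a = init_conv(6 * w, 2 * w),  dec2b = init_conv(2 * w, 2 * w),
      dec1a = init_conv(3 * w, w),      dec1b = init_conv(w, w),
      head  = init_conv(w, 1, k = 1)
    )
  }
  pars <- if (is.null(seed)) build() else with_seed(seed, build())
  attr(pars, "width") <- w
  attr(pars, "in_ch") <- in_ch
  pars
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

up2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

# backward of nearest-neighbour x2 upsampling: sum over each 2x2 block
up2_bwd <- function(g) {
  d <- dim(g)
  gi <- g[seq(1, d[1], 2), , , drop = FALSE] + g[seq(2, d[1], 2), , , drop = FALSE]
  gi[, seq(1, d[2], 2), , drop = FALSE] + gi[, seq(2, d[2], 2), , drop = FALSE]
}

cat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

# forward pass; keeps every intermediate needed by unet_backward
unet_forward <- function(pars, x) {
  H <- nrow(x); W <- ncol(x)
  if (H %% 8 != 0 || W %% 8 != 0)
    stop_param("x", "image sides must be divisible by 8")
  cv <- function(a, p) cpp_conv3_fwd(a, p$W, p$b)

  a0  <- array(x, c(H, W, dim_in <- attr(pars, "in_ch")))
  e1a <- relu(cv(a0, pars$enc1a));  e1 <- relu(cv(e1a, pars$enc1b))
  p1  <- cpp_maxpool2_fwd(e1)
  e2a <- relu(cv(p1$y, pars$enc2a)); e2 <- relu(cv(e2a, pars$enc2b))
  p2  <- cpp_maxpool2_fwd(e2)
  e3a <- relu(cv(p2$y, pars$enc3a)); e3 <- relu(cv(e3a, pars$enc3b))
  p3  <- cpp_maxpool2_fwd(e3)
  b1  <- relu(cv(p3$y, pars$bota));  b2 <- relu(cv(b1, pars$botb))
  c3  <- cat3(up2(b2), e3)
  d3a <- relu(cv(c3, pars$dec3a));   d3 <- relu(cv(d3a, pars$dec3b))
  c2  <- cat3(up2(d3), e2)
  d2a <- relu(cv(c2, pars$dec2a));   d2 <- relu(cv(d2a, pars$dec2b))
  c1  <- cat3(up2(d2), e1)
  d1a <- relu(cv(c1, pars$dec1a));   d1 <- relu(cv(d1a, pars$dec1b))
  nw  <- dim(d1)[3]
  z   <- matrix(matrix(d1, H * W, nw) %*% pars$head$W + pars$head$b, H, W)
  S   <- 1 / (1 + exp(-z))
  list(prob = S,
       cache = list(a0 = a0, e1a = e1a, e1 = e1, p1 = p1,
                    e2a = e2a, e2 = e2, p2 = p2,
                    e3a = e3a, e3 = e3, p3 = p3,
                    b1 = b1, b2 = b2, c3 = c3, d3a = d3a, d3 = d3,
                    c2 = c2, d2a = d2a, d2 = d2,
                    c1 = c1, d1a = d1a, d1 = d1, H = H, W = W))
}

#' Predict a probability map
#'
#' @param pars parameters from [unet_init()]
#' @param x H x W image matrix in `[0, 1]`; sides divisible by 8
#' @return H x W matrix of foreground probabilities in (0, 1)
#' @export
unet_predict <- function(pars, x) unet_forward(pars, x)$prob

# backward pass: dz is the gradient of the loss w.r.t. the sigmoid
# pre-activation (for mean BCE against target t this is (S - t) / n).
unet_backward <- function(pars, cache, dz) {
  H <- cache$H; W <- cache$W
  g <- list()
  # conv + relu block backward: y = relu(conv(x)); gy -> gx, accumulating grads
  blk <- function(x, p, y, gy, name) {
    gy[y <= 0] <- 0
    r <- cpp_conv3_bwd(x, p$W, gy)
    g[[name]] <<- list(W = r$gW, b = as.numeric(r$gb))
    r$gx
  }
  nw <- dim(cache$d1)[3]
  g$head <- list(W = t(matrix(cache$d1, H * W, nw)) %*% matrix(dz, H * W, 1),
                 b = sum(dz))
  gd1 <- array(matrix(dz, H * W, 1) %*% t(pars$head$W), c(H, W, nw))

  gd1a <- blk(cache$d1a, pars$dec1b, cache$d1, gd1, "dec1b")
  gc1  <- blk(cache$c1,  pars$dec1a, cache$d1a, gd1a, "dec1a")
  n_up1 <- dim(cache$d2)[3]
  gd2   <- up2_bwd(gc1[, , seq_len(n_up1), drop = FALSE])
  gskip1 <- gc1[, , n_up1 + seq_len(dim(gc1)[3] - n_up1), drop = FALSE]

  gd2a <- blk(cache$d2a, pars$dec2b, cache$d2, gd2, "dec2b")
  gc2  <- blk(cache$c2,  pars$dec2a, cache$d2a, gd2a, "dec2a")
  n_up2 <- dim(cache$d3)[3]
  gd3   <- up2_bwd(gc2[, , seq_len(n_up2), drop = FALSE])
  gskip2 <- gc2[, , n_up2 + seq_len(dim(gc2)[3] - n_up2), drop = FALSE]

  gd3a <- blk(cache$d3a, pars$dec3b, cache$d3, gd3, "dec3b")
  gc3  <- blk(cache$c3,  pars$dec3a, cache$d3a, gd3a, "dec3a")
  n_up3 <- dim(cache$b2)[3]
  gb2   <- up2_bwd(gc3[, , seq_len(n_up3), drop = FALSE])
  gskip3 <- gc3[, , n_up3 + seq_len(dim(gc3)[3] - n_up3), drop = FALSE]

  gb1  <- blk(cache$b1,  pars$botb, cache$b2, gb2, "botb")
  gp3  <- blk(cache$p3$y, pars$bota, cache$b1, gb1, "bota")
  ge3  <- cpp_maxpool2_bwd(gp3, cache$p3$idx, dim(cache$e3)[1], dim(cache$e3)[2]) +
          gskip3
  ge3a <- blk(cache$e3a, pars$enc3b, cache$e3, ge3, "enc3b")
  gp2  <- blk(cache$p2$y, pars$enc3a, cache$e3a, ge3a, "enc3a")
  ge2  <- cpp_maxpool2_bwd(gp2, cache$p2$idx, dim(cache$e2)[1], dim(cache$e2)[2]) +
          gskip2
  ge2a <- blk(cache$e2a, pars$enc2b, cache$e2, ge2, "enc2b")
  gp1  <- blk(cache$p1$y, pars$enc2a, cache$e2a, ge2a, "enc2a")
  ge1  <- cpp_maxpool2_bwd(gp1, cache$p1$idx, dim(cache$e1)[1], dim(cache$e1)[2]) +
          gskip1
  ge1a <- blk(cache$e1a, pars$enc1b, cache$e1, ge1, "enc1b")
  blk(cache$a0, pars$enc1a, cache$e1a, ge1a, "enc1a")
  g
}

# ---- Adam optimizer over a named list of {W, b} parameter pairs ----

adam_init <- function(pars) {
  zero_like <- function(p) list(W = p$W * 0, b = p$b * 0)
  list(t = 0L, m = lapply(pars, zero_like), v = lapply(pars, zero_like))
}

adam_step <- function(pars, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(pars)) {
    for (fld in c("W", "b")) {
      gr <- grads[[nm]][[fld]]
      state$m[[nm]][[fld]] <- beta1 * state$m[[nm]][[fld]] + (1 - beta1) * gr
      state$v[[nm]][[fld]] <- beta2 * state$v[[nm]][[fld]] + (1 - beta2) * gr^2
      mhat <- state$m[[nm]][[fld]] / bc1
      vhat <- state$v[[nm]][[fld]] / bc2
      pars[[nm]][[fld]] <- pars[[nm]][[fld]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(pars = pars, state = state)
}

# running average of parameter snapshots (stochastic weight averaging)
swa_accumulate <- function(avg, pars, n_prev) {
  if (is.null(avg)) return(pars)
  for (nm in names(pars)) {
    avg[[nm]]$W <- (avg[[nm]]$W * n_prev + pars[[nm]]$W) / (n_prev + 1)
    avg[[nm]]$b <- (avg[[nm]]$b * n_prev + pars[[nm]]$b) / (n_prev + 1)
  }
  avg
}
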