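#' @useDynLib vesselmend, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom
NULL

# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)) || is.null(dim(a)))
    stop(sprintf("%s must be matrices of identical shape", what), call. = FALSE)
  invisible(TRUE)
}

is_binary_mask <- function(m) {
  is.matrix(m) && all(m %in% c(0, 1))
}

check_binary_mask <- function(m, what = "mask") {
  if (!is_binary_mask(m))
    stop(sprintf("%s must be a binary matrix with values in {0, 1}", what),
         call. = FALSE)
  invisible(TRUE)
}
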