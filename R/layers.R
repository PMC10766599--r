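# Internal neural-network primitives. Activations are H x W x C x N arrays
# (column-major); forward functions return list(out, cache) and each backward
# consumes its cache. Gradients are verified against finite differences in the
# test suite.

#' @useDynLib veinnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

conv2d_forward <- function(x, w, stride = 1L, pad = NULL) {
  K <- dim(w)[1]
  if (is.null(pad)) pad <- (K - 1L) %/% 2L
  out <- .conv2d_fwd_cpp(x, w, as.integer(stride), as.integer(pad))
  list(out = out, cache = list(x = x, w = w, stride = stride, pad = pad))
}

conv2d_backward <- function(dout, cache) {
  g <- .conv2d_bwd_cpp(cache$x, cache$w, dout,
                       as.integer(cache$stride), as.integer(cache$pad))
  list(dx = g$dx, dw = g$dw)
}

maxpool_forward <- function(x, K = 3L, stride = 2L, pad = 1L) {
  r <- .maxpool_fwd_cpp(x, as.integer(K), as.integer(stride), as.integer(pad))
  list(out = r$out, cache = list(idx = r$idx, xdim = dim(x)))
}

maxpool_backward <- function(dout, cache) {
  .maxpool_bwd_cpp(dout, cache$idx, as.integer(cache$xdim))
}

relu_forward <- function(x) {
  out <- .relu_fwd_cpp(x)
  list(out = out, cache = out)
}

relu_backward <- function(dout, cache) {
  .relu_bwd_cpp(dout, cache)
}

# Batch normalization over (H, W, N) per channel. In training mode batch
# statistics are used and running statistics updated (momentum 0.1); in eval
# mode the running statistics are used.
bn_forward <- function(x, gamma, beta, running, training, eps = 1e-5,
                       momentum = 0.1) {
  d <- dim(x)
  M <- d[1] * d[2] * d[4]
  if (training) {
    st <- .channel_stats_cpp(x)
    mu <- st$sum / M
    v <- pmax(st$sumsq / M - mu^2, 0)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var +
      momentum * v * M / max(M - 1, 1)
  } else {
    mu <- running$mean
    v <- running$var
  }
  invstd <- 1 / sqrt(v + eps)
  sc <- gamma * invstd
  y <- .scale_shift_cpp(x, sc, beta - mu * sc)
  list(out = y, running = running,
       cache = list(x = x, mu = mu, invstd = invstd, gamma = gamma,
                    training = training))
}

bn_backward <- function(dout, cache) {
  .bn_bwd_cpp(dout, cache$x, cache$mu, cache$invstd, cache$gamma,
              cache$training)
}

linear_forward <- function(x, w, b) {
  # x: D x N, w: D x K, b: K -> out K x N
  out <- crossprod(w, x) + b
  list(out = out, cache = list(x = x, w = w))
}

linear_backward <- function(dout, cache) {
  list(dx = cache$w %*% dout,
       dw = cache$x %*% t(dout),
       db = rowSums(dout))
}

# He-style initialization for a conv kernel of dim (K, K, Cg, Cout).
init_conv <- function(K, Cg, Cout, rng_sd = NULL) {
  fan_in <- K * K * Cg
  sd <- sqrt(2 / fan_in)
  array(stats::rnorm(K * K * Cg * Cout, sd = sd), dim = c(K, K, Cg, Cout))
}

new_bn_params <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C))
}

new_bn_running <- function(C) {
  list(mean = rep(0, C), var = rep(1, C))
}
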