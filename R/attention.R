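# Scale-aware attention: the scale descriptor module (SDM) turns the 4C-channel
# multi-scale map of a pyramidal convolution into a row-stochastic C x C
# cross-scale matrix phi; the scale attention module (SAM) re-aggregates the
# compressed per-scale features through phi and adds them back through a gated
# skip connection.

row_softmax <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Compute the cross-scale descriptor matrix
#'
#' Two independent 1x1 reductions project the `4C`-channel multi-scale map to
#' `C` channels each, giving `Omega` (reshaped `C x N`) and `Theta` (`N x C`,
#' `N = H * W`). Their product, row-softmaxed, is the `C x C` scale descriptor
#' `phi`: entry `(a, b)` is the weight with which descriptor channel `a`
#' attends to channel `b`, and the 4x4 block `phi[i, j]` couples scale `i` to
#' scale `j`. Every row of `phi` sums to one.
#'
#' @param multi_scale_map Channels-first array `(4C, H, W)` (the concatenated
#'   pyramidal-convolution output).
#' @param reduction_weights List with matrices `omega` and `theta`, each
#'   `4C x C`, holding the 1x1 reduction weights.
#' @return An object of class `scale_descriptor` with elements `phi`
#'   (`C x C`), `C` and `source_spatial`.
#' @export
compute_scale_descriptor <- function(multi_scale_map, reduction_weights) {
  d <- dim(multi_scale_map)
  if (length(d) != 3) stop("multi_scale_map must be (channels, H, W)")
  C4 <- d[1]
  if (C4 %% 4 != 0) stop("channel count must be divisible by 4")
  N <- d[2] * d[3]
  if (N == 0) stop("empty spatial extent")
  C <- ncol(reduction_weights$omega)
  if (nrow(reduction_weights$omega) != C4 ||
      !identical(dim(reduction_weights$theta), dim(reduction_weights$omega)))
    stop("reduction weights must be (4C x C) matrices")
  X <- matrix(multi_scale_map, nrow = C4)        # C4 x N
  Omega <- crossprod(reduction_weights$omega, X) # C x N
  Theta <- t(crossprod(reduction_weights$theta, X)) # N x C
  phi <- row_softmax(Omega %*% Theta)
  structure(list(phi = phi, C = C, source_spatial = d[2:3]),
            class = "scale_descriptor")
}

#' Refine per-scale features with a scale descriptor
#'
#' Each refined scale is the descriptor-weighted aggregation of all scales
#' plus the original feature (skip connection):
#' `refined_i = gate * sum_j phi[i, j] %*% F_j + F_i`. At `gate = 0` the
#' input is returned unchanged, which is how the no-attention ablation is a
#' strict special case of the attended block.
#'
#' @param descriptor A [compute_scale_descriptor()] result whose `C` matches
#'   the features' total channel count.
#' @param features Either a channels-first `(C, H, W)` array (scales
#'   concatenated smallest kernel first) or a list of four `(C/4, H, W)`
#'   arrays.
#' @param gate Scalar weight on the attention path.
#' @return Refined features in the same form as `features`.
#' @export
scale_attention_refine <- function(descriptor, features, gate = 1) {
  as_list <- is.list(features)
  f <- if (as_list) abind_channels(features) else features
  d <- dim(f)
  if (d[1] != descriptor$C)
    stop("feature channel count does not match the descriptor")
  Fm <- matrix(f, nrow = d[1])                   # C x N
  out <- gate * (descriptor$phi %*% Fm) + Fm
  dim(out) <- d
  if (as_list) split_scales(out, 4L) else out
}

abind_channels <- function(maps) {
  d <- dim(maps[[1]])
  out <- array(0, dim = c(sum(vapply(maps, function(m) dim(m)[1], 0)), d[2], d[3]))
  at <- 0L
  for (m in maps) {
    out[at + seq_len(dim(m)[1]), , ] <- m
    at <- at + dim(m)[1]
  }
  out
}

split_scales <- function(f, n) {
  C <- dim(f)[1] %/% n
  lapply(seq_len(n), function(i) f[(i - 1L) * C + seq_len(C), , , drop = FALSE])
}

# ---- batched internals used by the network ----

init_sdm_params <- function(C4, C) {
  sd <- sqrt(2 / C4)
  list(omega = array(stats::rnorm(C4 * C, sd = sd), dim = c(1, 1, C4, C)),
       theta = array(stats::rnorm(C4 * C, sd = sd), dim = c(1, 1, C4, C)),
       gate = 0)
}

# p: (H, W, 4C, N) multi-scale map; f: (H, W, C, N) compressed features.
# Returns refined f and caches for the backward pass. Per-sample matrices
# are kept in (HW x C) orientation throughout, so reshapes are free (the
# (HW, C, N) flattening coincides with the (H, W, C, N) array layout) and no
# large transposes are taken: with OmR = Omega^T and ThR = Theta,
# phi = softmax(OmR^T ThR) and the refined map is FR + gate * FR phi^T.
sa_forward <- function(p, f, params) {
  ro <- conv2d_forward(p, params$omega)
  rt <- conv2d_forward(p, params$theta)
  r <- .sa_fwd_cpp(ro$out, rt$out, f, params$gate)
  list(out = r$out,
       cache = list(ro = ro, rt = rt, f = f, phis = r$phis, Ms = r$Ms,
                    gate = params$gate))
}

sa_backward <- function(dout, cache) {
  r <- .sa_bwd_cpp(dout, cache$f, cache$ro$out, cache$rt$out,
                   cache$phis, cache$Ms, cache$gate)
  go <- conv2d_backward(r$domega, cache$ro$cache)
  gt <- conv2d_backward(r$dtheta, cache$rt$cache)
  list(df = r$df, dp = go$dx + gt$dx,
       grads = list(omega = go$dw, theta = gt$dw, gate = r$dgate))
}

# ---- residual scale-aware pyramidal convolution block ----

# Shared (non-attention) weights only; SA parameters are added afterwards
# by add_sa_params() so that, for a fixed seed, the attended and
# no-attention variants share identical shared-weight initializations --
# with the gate at 0 they then start as the same function, which makes
# ablation comparisons exactly paired.
init_block_params <- function(in_channels, width, out_channels, stride,
                              kernel_sizes = c(3L, 5L, 7L, 9L),
                              groups = c(1L, 4L, 8L, 16L)) {
  spec <- pyconv_spec(in_channels, kernel_sizes,
                      out_channels = rep(width, length(kernel_sizes)),
                      groups = groups, stride = stride)
  C4 <- width * length(kernel_sizes)
  p <- list(
    spec = spec,
    py = init_pyconv_params(spec),
    bn_py = new_bn_params(C4),
    w_compress = init_conv(1L, C4, width),
    bn_c = new_bn_params(width),
    w_expand = init_conv(1L, width, out_channels),
    bn_e = new_bn_params(out_channels)
  )
  if (in_channels != out_channels || stride != 1L) {
    p$w_short <- init_conv(1L, in_channels, out_channels)
    p$bn_s <- new_bn_params(out_channels)
  }
  p
}

add_sa_params <- function(params) {
  C4 <- sum(params$spec$out_channels)
  params$sa <- init_sdm_params(C4, params$spec$out_channels[1])
  params
}

init_block_buffers <- function(params) {
  C4 <- sum(params$spec$out_channels)
  b <- list(bn_py = new_bn_running(C4),
            bn_c = new_bn_running(dim(params$w_compress)[4]),
            bn_e = new_bn_running(dim(params$w_expand)[4]))
  if (!is.null(params$w_short))
    b$bn_s <- new_bn_running(dim(params$w_short)[4])
  b
}

block_forward <- function(x, params, buffers, training, attention) {
  cc <- list()
  py <- pyconv_forward(x, params$py, params$spec); cc$py <- py$cache
  b1 <- bn_forward(py$out, params$bn_py$gamma, params$bn_py$beta,
                   buffers$bn_py, training); buffers$bn_py <- b1$running
  cc$bn_py <- b1$cache
  r1 <- relu_forward(b1$out); cc$r1 <- r1$cache
  cp <- conv2d_forward(r1$out, params$w_compress); cc$cp <- cp$cache
  b2 <- bn_forward(cp$out, params$bn_c$gamma, params$bn_c$beta,
                   buffers$bn_c, training); buffers$bn_c <- b2$running
  cc$bn_c <- b2$cache
  r2 <- relu_forward(b2$out); cc$r2 <- r2$cache
  h <- r2$out
  if (attention == "sa") {
    sa <- sa_forward(r1$out, h, params$sa)
    h <- sa$out
    cc$sa <- sa$cache
  }
  ex <- conv2d_forward(h, params$w_expand); cc$ex <- ex$cache
  b3 <- bn_forward(ex$out, params$bn_e$gamma, params$bn_e$beta,
                   buffers$bn_e, training); buffers$bn_e <- b3$running
  cc$bn_e <- b3$cache
  if (!is.null(params$w_short)) {
    sh <- conv2d_forward(x, params$w_short, stride = params$spec$stride,
                         pad = 0L); cc$sh <- sh$cache
    bs <- bn_forward(sh$out, params$bn_s$gamma, params$bn_s$beta,
                     buffers$bn_s, training); buffers$bn_s <- bs$running
    cc$bn_s <- bs$cache
    shortcut <- bs$out
  } else {
    shortcut <- x
  }
  ro <- relu_forward(b3$out + shortcut); cc$ro <- ro$cache
  list(out = ro$out, cache = cc, buffers = buffers)
}

block_backward <- function(dout, params, cache, attention) {
  g <- list()
  dsum <- relu_backward(dout, cache$ro)
  b3 <- bn_backward(dsum, cache$bn_e)
  g$bn_e <- list(gamma = b3$dgamma, beta = b3$dbeta)
  ex <- conv2d_backward(b3$dx, cache$ex)
  g$w_expand <- ex$dw
  dh <- ex$dx
  dr1_extra <- NULL
  if (attention == "sa") {
    sa <- sa_backward(dh, cache$sa)
    dh <- sa$df
    dr1_extra <- sa$dp
    g$sa <- sa$grads
  }
  dr2 <- relu_backward(dh, cache$r2)
  b2 <- bn_backward(dr2, cache$bn_c)
  g$bn_c <- list(gamma = b2$dgamma, beta = b2$dbeta)
  cp <- conv2d_backward(b2$dx, cache$cp)
  g$w_compress <- cp$dw
  dr1 <- cp$dx
  if (!is.null(dr1_extra)) dr1 <- dr1 + dr1_extra
  dr1 <- relu_backward(dr1, cache$r1)
  b1 <- bn_backward(dr1, cache$bn_py)
  g$bn_py <- list(gamma = b1$dgamma, beta = b1$dbeta)
  py <- pyconv_backward(b1$dx, cache$py)
  g$py <- py$dws
  dx <- py$dx
  if (!is.null(params$w_short)) {
    bs <- bn_backward(dsum, cache$bn_s)
    g$bn_s <- list(gamma = bs$dgamma, beta = bs$dbeta)
    sh <- conv2d_backward(bs$dx, cache$sh)
    g$w_short <- sh$dw
    dx <- dx + sh$dx
  } else {
    dx <- dx + dsum
  }
  list(dx = dx, grads = g)
}

#' Build a residual scale-aware pyramidal convolution block
#'
#' The block computes: pyramidal convolution (4 scales, `4C` channels) ->
#' 1x1 compression to the single-scale width `C` -> scale-aware attention
#' refinement (if enabled) -> 1x1 expansion to `out_channels` -> identity
#' shortcut (1x1-projected when the channel count or stride changes) -> ReLU.
#' Batch normalization follows every convolution. `attention = "none"` drops
#' the descriptor/refinement path entirely and is the ablation variant; with
#' the gate at its initial value 0 the attended block computes exactly the
#' same function.
#'
#' @param in_channels,out_channels Block input/output channel counts.
#' @param width Single-scale channel count `C` (each pyramid level emits
#'   `width` channels). Must be divisible by 4 and by the group counts.
#' @param stride Spatial stride (2 for downsampling blocks).
#' @param attention `"none"` or `"sa"`.
#' @param kernel_sizes,groups Pyramid schedule, as in [pyconv_spec()].
#' @return An object of class `rasapyconv_block`.
#' @export
build_rasapyconv_block <- function(in_channels, out_channels, width = out_channels,
                                   stride = 1L, attention = c("sa", "none"),
                                   kernel_sizes = c(3L, 5L, 7L, 9L),
                                   groups = c(1L, 4L, 8L, 16L)) {
  attention <- match.arg(attention)
  if (width %% 4 != 0) stop("width must be divisible by 4")
  params <- init_block_params(in_channels, width, out_channels, stride,
                              kernel_sizes, groups)
  if (attention == "sa") params <- add_sa_params(params)
  structure(list(params = params, buffers = init_block_buffers(params),
                 attention = attention),
            class = "rasapyconv_block")
}

#' Apply a residual block to one feature map
#'
#' Runs the block in evaluation mode (running batch-norm statistics) on a
#' single channels-first map.
#'
#' @param block A [build_rasapyconv_block()] handle.
#' @param x A `(C_in, H, W)` array.
#' @return A `(C_out, H', W')` array.
#' @export
rasapyconv_apply <- function(block, x) {
  stopifnot(inherits(block, "rasapyconv_block"), length(dim(x)) == 3)
  xb <- aperm(x, c(2, 3, 1))
  dim(xb) <- c(dim(xb), 1L)
  out <- block_forward(xb, block$params, block$buffers, training = FALSE,
                       attention = block$attention)$out
  aperm(array(out, dim = dim(out)[1:3]), c(3, 1, 2))
}
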