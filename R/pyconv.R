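#' Specify a pyramidal convolution layer
#'
#' A pyramidal convolution runs several grouped convolutions in parallel over
#' the same input, with kernel size increasing and kernel depth (channels per
#' group) decreasing from the first to the last level. The level outputs are
#' concatenated along the channel axis, so a single layer sees the input at
#' several receptive-field sizes at once.
#'
#' @param in_channels Number of input feature channels.
#' @param kernel_sizes Odd, strictly increasing kernel sizes, one per level.
#' @param out_channels Output channels per level (same length as
#'   `kernel_sizes`). Default: an equal split of `in_channels`.
#' @param groups Number of groups per level; each must divide both
#'   `in_channels` and the level's `out_channels`. The per-level kernel depth
#'   is `in_channels / groups`.
#' @param stride Common spatial stride for all levels.
#' @return An object of class `pyconv_spec`.
#' @examples
#' pyconv_spec(64)
#' @export
pyconv_spec <- function(in_channels,
                        kernel_sizes = c(3L, 5L, 7L, 9L),
                        out_channels = NULL,
                        groups = c(1L, 4L, 8L, 16L),
                        stride = 1L) {
  if (in_channels < 1) stop("in_channels must be positive")
  n <- length(kernel_sizes)
  if (missing(groups) && n <= 4) groups <- groups[seq_len(n)]
  if (is.null(out_channels)) {
    if (in_channels %% n != 0)
      stop("in_channels not divisible by the number of levels; give out_channels")
    out_channels <- rep(in_channels %/% n, n)
  }
  if (length(out_channels) != n || length(groups) != n)
    stop("kernel_sizes, out_channels and groups must have equal length")
  if (any(kernel_sizes %% 2 == 0)) stop("kernel sizes must be odd")
  if (n > 1 && any(diff(kernel_sizes) <= 0))
    stop("kernel sizes must strictly increase across levels")
  if (any(out_channels < 1)) stop("out_channels must be positive")
  for (l in seq_len(n)) {
    if (in_channels %% groups[l] != 0 || out_channels[l] %% groups[l] != 0)
      stop(sprintf(
        "level %d: groups (%d) must divide in_channels (%d) and out_channels (%d)",
        l, groups[l], in_channels, out_channels[l]))
  }
  structure(list(in_channels = as.integer(in_channels),
                 kernel_sizes = as.integer(kernel_sizes),
                 out_channels = as.integer(out_channels),
                 groups = as.integer(groups),
                 stride = as.integer(stride)),
            class = "pyconv_spec")
}

init_pyconv_params <- function(spec) {
  lapply(seq_along(spec$kernel_sizes), function(l) {
    init_conv(spec$kernel_sizes[l], spec$in_channels %/% spec$groups[l],
              spec$out_channels[l])
  })
}

pyconv_forward <- function(x, weights, spec) {
  outs <- vector("list", length(weights))
  caches <- vector("list", length(weights))
  for (l in seq_along(weights)) {
    r <- conv2d_forward(x, weights[[l]], stride = spec$stride)
    outs[[l]] <- r$out
    caches[[l]] <- r$cache
  }
  d <- dim(outs[[1]])
  out <- array(0, dim = c(d[1], d[2], sum(spec$out_channels), d[4]))
  at <- 0L
  for (l in seq_along(outs)) {
    co <- spec$out_channels[l]
    out[, , at + seq_len(co), ] <- outs[[l]]
    at <- at + co
  }
  list(out = out, cache = list(caches = caches, spec = spec))
}

pyconv_backward <- function(dout, cache) {
  spec <- cache$spec
  dx <- NULL
  dws <- vector("list", length(cache$caches))
  at <- 0L
  for (l in seq_along(cache$caches)) {
    co <- spec$out_channels[l]
    dl <- dout[, , at + seq_len(co), , drop = FALSE]
    at <- at + co
    g <- conv2d_backward(dl, cache$caches[[l]])
    dws[[l]] <- g$dw
    dx <- if (is.null(dx)) g$dx else dx + g$dx
  }
  list(dx = dx, dws = dws)
}

#' Build a pyramidal convolution layer
#'
#' Instantiates (with seeded random weights) the layer described by a
#' [pyconv_spec()]. The returned handle can be applied to a single
#' channels-first feature map with [pyconv_apply()]; outputs of all levels are
#' concatenated smallest kernel first.
#'
#' @param spec A [pyconv_spec()].
#' @return An object of class `pyconv_layer` carrying the per-level weights.
#' @examples
#' layer <- build_pyconv(pyconv_spec(8, 3, 8, 1))
#' y <- pyconv_apply(layer, array(0, c(8, 5, 5)))
#' dim(y)
#' @export
build_pyconv <- function(spec) {
  stopifnot(inherits(spec, "pyconv_spec"))
  structure(list(spec = spec, weights = init_pyconv_params(spec)),
            class = "pyconv_layer")
}

#' Apply a pyramidal convolution layer to one feature map
#'
#' @param layer A [build_pyconv()] handle.
#' @param x A channels-first array `(C, H, W)` with `C` equal to the spec's
#'   `in_channels`.
#' @return A `(sum(out_channels), H', W')` array; at stride 1 the spatial size
#'   is preserved (same padding).
#' @export
pyconv_apply <- function(layer, x) {
  stopifnot(inherits(layer, "pyconv_layer"), length(dim(x)) == 3)
  if (dim(x)[1] != layer$spec$in_channels)
    stop("input channel count does not match the spec")
  xb <- aperm(x, c(2, 3, 1))
  dim(xb) <- c(dim(xb), 1L)
  out <- pyconv_forward(xb, layer$weights, layer$spec)$out
  aperm(array(out, dim = dim(out)[1:3]), c(3, 1, 2))
}

check_counts_args <- function(in_channels, kernel_sizes, out_channels) {
  if (in_channels < 1) stop("in_channels must be positive")
  if (any(out_channels < 0)) stop("out_channels must be non-negative")
  if (length(kernel_sizes) != length(out_channels))
    stop("kernel_sizes and out_channels must have equal length")
  if (length(kernel_sizes) > 1 && any(diff(kernel_sizes) <= 0))
    stop("kernel sizes must be ascending")
}

#' Analytic parameter count of a pyramidal convolution
#'
#' Counts learnable weights under the idealized depth schedule in which level
#' `i` uses kernel depth `in_channels * K1^2 / Ki^2` (no bias terms). Each
#' per-level term then simplifies to `K1^2 * in_channels * out_channels[i]`,
#' i.e. every level costs exactly as much as a standard `K1 x K1` convolution
#' with the same channel counts -- the pyramid widens the receptive field for
#' free. Realized layers with integer group counts are counted by
#' [pyconv_realized_params()].
#'
#' @param in_channels Input channel count.
#' @param kernel_sizes Ascending kernel sizes.
#' @param out_channels Per-level output channel counts.
#' @return A list with `per_level` (one term per level) and `total`.
#' @examples
#' pyconv_param_count(64, c(3, 5, 7, 9), rep(16, 4))$total  # 36864
#' @export
pyconv_param_count <- function(in_channels, kernel_sizes, out_channels) {
  check_counts_args(in_channels, kernel_sizes, out_channels)
  K1 <- kernel_sizes[1]
  per <- kernel_sizes^2 * (in_channels * K1^2 / kernel_sizes^2) * out_channels
  list(per_level = per, total = sum(per))
}

#' Analytic FLOP count of a pyramidal convolution
#'
#' Multiply--accumulate count over an `H x W` output map under the same
#' idealized depth schedule as [pyconv_param_count()]; each per-level term is
#' the corresponding parameter term times `H * W`.
#'
#' @inheritParams pyconv_param_count
#' @param H,W Spatial size of the output feature map.
#' @return A list with `per_level` and `total`.
#' @export
pyconv_flop_count <- function(in_channels, kernel_sizes, out_channels, H, W) {
  p <- pyconv_param_count(in_channels, kernel_sizes, out_channels)
  list(per_level = p$per_level * H * W, total = p$total * H * W)
}

#' Realized parameter count of a pyramidal convolution layer
#'
#' Counts the actual learnable weights of the layer a [pyconv_spec()] builds:
#' level `i` holds `Ki^2 * (in_channels / groups[i]) * out_channels[i]`
#' weights (bias-free). This equals the idealized [pyconv_param_count()]
#' exactly when `Ki^2 / K1^2` is an integer and `groups[i]` equals that ratio.
#'
#' @param spec A [pyconv_spec()].
#' @return A list with `per_level` and `total`.
#' @export
pyconv_realized_params <- function(spec) {
  per <- spec$kernel_sizes^2 * (spec$in_channels / spec$groups) *
    spec$out_channels
  list(per_level = per, total = sum(per))
}
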