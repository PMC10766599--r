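# Verification backbone: stem convolution, four stages of residual
# scale-aware pyramidal-convolution blocks, a GeM global descriptor and a
# linear classification head. The embedding path (stem -> stages -> GeM) has
# no dependence on the head at inference.

GEM_FLOOR <- 1e-6

#' Network configuration
#'
#' Describes the verification backbone. The default profile is compact
#' (4 stages of one block each, widths 32/64/128/256) so that full training
#' runs are practical on a single CPU; a deeper profile in the style of larger
#' residual networks is obtained by raising `stage_widths` and
#' `blocks_per_stage`. The embedding size always equals the final stage width.
#'
#' @param n_classes Number of training classes (size of the softmax head).
#' @param input_size Spatial input size; images are resized to this and
#'   channel-replicated to 3 channels (224 reproduces the standard resize
#'   contract; 96 is the CPU-scale profile used by the package's own
#'   experiments).
#' @param stem_channels Channels of the stem convolution (7x7, stride 2,
#'   followed by 3x3 stride-2 max pooling when `stem_pool` is `TRUE`).
#' @param stem_pool Apply the stride-2 max pooling after the stem (the
#'   default). Disabling it keeps the first stage at half the input
#'   resolution, which preserves fine vein detail at small input sizes at
#'   roughly 4x the stage-1 compute and activation memory.
#' @param stage_widths Single-scale width of each stage's blocks.
#' @param blocks_per_stage Number of residual blocks per stage.
#' @param attention `"sa"` (scale-aware attention) or `"none"` (ablation).
#' @param gem_p_init Initial value of the learnable per-channel GeM pooling
#'   exponents.
#' @param kernel_sizes,groups Pyramid schedule shared by all blocks.
#' @return An object of class `veinnet_config`.
#' @export
network_config <- function(n_classes,
                           input_size = 224L,
                           stem_channels = 32L,
                           stem_pool = TRUE,
                           stage_widths = c(32L, 64L, 128L, 256L),
                           blocks_per_stage = c(1L, 1L, 1L, 1L),
                           attention = c("sa", "none"),
                           gem_p_init = 3,
                           kernel_sizes = c(3L, 5L, 7L, 9L),
                           groups = c(1L, 4L, 8L, 16L)) {
  attention <- match.arg(attention)
  stopifnot(n_classes >= 2, length(stage_widths) == length(blocks_per_stage))
  structure(list(n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 stem_channels = as.integer(stem_channels),
                 stem_pool = isTRUE(stem_pool),
                 stage_widths = as.integer(stage_widths),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 attention = attention,
                 embedding_size = as.integer(stage_widths[length(stage_widths)]),
                 gem_p_init = gem_p_init,
                 kernel_sizes = as.integer(kernel_sizes),
                 groups = as.integer(groups)),
            class = "veinnet_config")
}

#' Build the verification network
#'
#' Instantiates all learnable parameters (seeded by the caller's RNG state)
#' for the configuration. The model maps a batch of `(H, W, 3, N)` images to
#' an embedding matrix and class logits; [embed()] returns unit-normalized
#' embeddings for verification scoring.
#'
#' @param config A [network_config()].
#' @return An object of class `veinnet_model`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "veinnet_config"))
  if (!config$attention %in% c("sa", "none"))
    stop("unknown attention mode")
  params <- list(stem = init_conv(7L, 3L, config$stem_channels),
                 bn_stem = new_bn_params(config$stem_channels))
  buffers <- list(bn_stem = new_bn_running(config$stem_channels))
  in_ch <- config$stem_channels
  for (s in seq_along(config$stage_widths)) {
    w <- config$stage_widths[s]
    for (b in seq_len(config$blocks_per_stage[s])) {
      stride <- if (s > 1 && b == 1) 2L else 1L
      key <- sprintf("stage%d_block%d", s, b)
      params[[key]] <- init_block_params(in_ch, w, w, stride,
                                         config$kernel_sizes, config$groups)
      buffers[[key]] <- init_block_buffers(params[[key]])
      in_ch <- w
    }
  }
  D <- config$embedding_size
  params$gem_p <- rep(config$gem_p_init, D)
  params$bn_emb <- new_bn_params(D)
  buffers$bn_emb <- new_bn_running(D)
  params$head <- list(
    w = matrix(stats::rnorm(D * config$n_classes, sd = sqrt(1 / D)),
               nrow = D),
    b = rep(0, config$n_classes))
  # attention parameters are drawn last, on a fork of the RNG stream that is
  # restored afterwards: for a fixed seed the attended and no-attention
  # builds share identical shared-weight initializations AND identical
  # downstream randomness (batches, augmentation), so ablation comparisons
  # are exactly paired
  if (config$attention == "sa") {
    withr::with_preserve_seed({
      for (key in block_keys(config))
        params[[key]] <- add_sa_params(params[[key]])
    })
  }
  structure(list(config = config, params = params, buffers = buffers),
            class = "veinnet_model")
}

block_keys <- function(config) {
  unlist(lapply(seq_along(config$stage_widths), function(s)
    sprintf("stage%d_block%d", s, seq_len(config$blocks_per_stage[s]))))
}

# x: (H, W, 3, N) in [0, 1]. Returns raw embeddings (D x N), logits (K x N)
# and caches. Mutates no state; updated BN buffers are returned.
network_forward <- function(model, x, training = FALSE) {
  p <- model$params; buf <- model$buffers
  cc <- list()
  st <- conv2d_forward(x, p$stem, stride = 2L, pad = 3L); cc$stem <- st$cache
  b <- bn_forward(st$out, p$bn_stem$gamma, p$bn_stem$beta, buf$bn_stem,
                  training)
  buf$bn_stem <- b$running; cc$bn_stem <- b$cache
  r <- relu_forward(b$out); cc$r_stem <- r$cache
  if (model$config$stem_pool) {
    mp <- maxpool_forward(r$out); cc$mp <- mp$cache
    h <- mp$out
  } else {
    h <- r$out
  }
  for (key in block_keys(model$config)) {
    bf <- block_forward(h, p[[key]], buf[[key]], training,
                        model$config$attention)
    h <- bf$out; buf[[key]] <- bf$buffers; cc[[key]] <- bf$cache
  }
  gm <- gem_forward(h, p$gem_p); cc$gem <- gm$cache
  # batch-norm neck on the descriptor: normalized embeddings feed both the
  # classifier and the verification score
  e4 <- gm$out; dim(e4) <- c(1L, 1L, dim(gm$out))
  be <- bn_forward(e4, p$bn_emb$gamma, p$bn_emb$beta, buf$bn_emb, training)
  buf$bn_emb <- be$running; cc$bn_emb <- be$cache
  emb <- matrix(be$out, nrow = dim(gm$out)[1])
  hd <- linear_forward(emb, p$head$w, p$head$b); cc$head <- hd$cache
  list(embedding = emb, logits = hd$out, caches = cc, buffers = buf)
}

# dembedding: D x N, dlogits: K x N (either may be NULL).
network_backward <- function(model, caches, dembedding = NULL, dlogits = NULL) {
  g <- list()
  demb <- dembedding
  if (!is.null(dlogits)) {
    hb <- linear_backward(dlogits, caches$head)
    g$head <- list(w = hb$dw, b = hb$db)
    demb <- if (is.null(demb)) hb$dx else demb + hb$dx
  } else {
    g$head <- list(w = caches$head$w * 0, b = rep(0, ncol(caches$head$w)))
  }
  d4 <- demb; dim(d4) <- c(1L, 1L, dim(demb))
  bb0 <- bn_backward(d4, caches$bn_emb)
  g$bn_emb <- list(gamma = bb0$dgamma, beta = bb0$dbeta)
  dgem <- matrix(bb0$dx, nrow = dim(demb)[1])
  gb <- gem_backward(dgem, caches$gem)
  g$gem_p <- gb$dp
  dh <- gb$dx
  for (key in rev(block_keys(model$config))) {
    bb <- block_backward(dh, model$params[[key]], caches[[key]],
                         model$config$attention)
    g[[key]] <- bb$grads
    dh <- bb$dx
  }
  if (model$config$stem_pool) dh <- maxpool_backward(dh, caches$mp)
  dh <- relu_backward(dh, caches$r_stem)
  bs <- bn_backward(dh, caches$bn_stem)
  g$bn_stem <- list(gamma = bs$dgamma, beta = bs$dbeta)
  sc <- conv2d_backward(bs$dx, caches$stem)
  g$stem <- sc$dw
  g
}

# ---- generalized-mean pooling ----

gem_forward <- function(x, p) {
  d <- dim(x)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  if (any(p <= 0)) stop("GeM exponents must be positive")
  xc <- pmax(x, GEM_FLOOR)
  xm <- matrix(xc, nrow = HW)                 # columns (c, n)
  pv <- rep(p, times = N)
  xp <- sweep(xm, 2L, pv, "^")
  m <- colMeans(xp)
  f <- m^(1 / pv)
  out <- matrix(f, nrow = C)
  list(out = out,
       cache = list(xm = xm, xp = xp, m = m, f = f, pv = pv, d = d,
                    clamped = matrix(x, nrow = HW) < GEM_FLOOR))
}

gem_backward <- function(dout, cache) {
  d <- cache$d
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  dv <- as.vector(dout)                       # length C*N, column order (c, n)
  # d f / d x = f^(1-p) x^(p-1) / HW on the unclamped region
  coef <- dv * cache$f^(1 - cache$pv) / HW
  dxm <- sweep(cache$xp / cache$xm, 2L, coef, "*")  # xp / xm = x^(p-1)
  dxm[cache$clamped] <- 0
  dx <- array(dxm, dim = d)
  # d f / d p = f * ( sum(x^p log x) / (p sum(x^p)) - log(m) / p^2 )
  slog <- colSums(cache$xp * log(cache$xm))
  dfdp <- cache$f * (slog / (cache$pv * cache$m * HW) -
                       log(cache$m) / cache$pv^2)
  dp_all <- dv * dfdp
  dim(dp_all) <- c(C, N)
  list(dx = dx, dp = rowSums(dp_all))
}

#' Generalized-mean (GeM) pooling of a feature map
#'
#' Pools each channel of a non-negative feature map to a single value
#' `f_c = (mean(x^p_c))^(1/p_c)` with a learnable per-channel exponent.
#' `p_c = 1` is exact global average pooling (SPoC); `p_c -> Inf` approaches
#' global max pooling (MAC). Values are clamped to a floor of `1e-6` before
#' exponentiation for numerical stability.
#'
#' @param feature_map Channels-first array `(C, H, W)` with non-negative
#'   entries.
#' @param exponents Positive pooling exponents, length `C` or 1 (recycled).
#' @return An object of class `global_descriptor` with `values` (length `C`)
#'   and `exponents`.
#' @examples
#' m <- array(abs(rnorm(4 * 5 * 5)), c(4, 5, 5))
#' gem_pool(m, 1)$values  # equals per-channel means
#' @export
gem_pool <- function(feature_map, exponents = 3) {
  stopifnot(length(dim(feature_map)) == 3)
  C <- dim(feature_map)[1]
  p <- rep_len(exponents, C)
  if (any(p <= 0)) stop("GeM exponents must be positive")
  x <- aperm(feature_map, c(2, 3, 1))
  dim(x) <- c(dim(x), 1L)
  f <- gem_forward(x, p)$out[, 1]
  structure(list(values = f, exponents = p), class = "global_descriptor")
}

#' Embed images with a model
#'
#' Runs the network in evaluation mode (deterministic: running batch-norm
#' statistics, no augmentation) and returns L2-normalized GeM descriptors,
#' one row per image, for verification scoring.
#'
#' @param model A [build_network()] model.
#' @param x Either a preprocessed batch array `(H, W, 3, N)` in `[0, 1]` or a
#'   list of raw grayscale images (matrices in `[0, 255]`), which are passed
#'   through [preprocess()] first.
#' @param batch_size Images embedded per forward pass.
#' @return An `N x D` matrix of unit-norm embeddings.
#' @export
embed <- function(model, x, batch_size = 64L) {
  stopifnot(inherits(model, "veinnet_model"))
  if (is.list(x) && !is.array(x))
    x <- preprocess_batch(x, model$config$input_size)
  N <- dim(x)[4]
  out <- matrix(0, nrow = N, ncol = model$config$embedding_size)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    fw <- network_forward(model, x[, , , idx, drop = FALSE], training = FALSE)
    out[idx, ] <- t(fw$embedding)
  }
  nrm <- sqrt(rowSums(out^2))
  nrm[nrm == 0] <- 1
  out / nrm
}

# Number of learnable parameters of a model.
count_params <- function(model) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      for (el in x) walk(el)
    } else if (is.numeric(x)) {
      n <<- n + length(x)
    }
  }
  # spec entries inside block param lists are not learnable
  strip <- function(p) {
    if (is.list(p)) {
      p$spec <- NULL
      lapply(p, strip)
    } else p
  }
  walk(strip(model$params))
  n
}
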