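# Seeded generator of synthetic finger-vein ROI images. Each class owns a
# fixed vein topology (smooth dark curves on a brighter tissue background,
# mimicking near-infrared absorption by deoxygenated hemoglobin); samples of
# a class add geometric jitter, a multiplicative illumination field and
# sensor noise, emulating repeated acquisitions of the same finger.

#' Synthetic dataset configuration
#'
#' Defaults follow the structure of public finger-vein ROI collections: many
#' classes (fingers) with 6 samples each, longitudinal dark veins, and
#' intra-class jitter on the scale of the standard augmentation policy
#' (+/- 2.5 degrees rotation, +/- 5% shifts). The desk-scale default
#' (20 classes, 64 x 64) keeps unit tests fast; `synth_profile("smoke")`
#' gives the 100-class, 96 x 96 profile used for end-to-end training
#' experiments.
#'
#' @param n_classes,samples_per_class Dataset shape.
#' @param height,width Image size in pixels.
#' @param n_veins Range (min, max) of vein curves per class.
#' @param thickness Range of vein half-thickness in pixels.
#' @param contrast Peak vein darkening in gray levels.
#' @param noise_sigma Standard deviation of additive Gaussian sensor noise
#'   (gray levels).
#' @param rotation,shift Intra-class jitter ranges: degrees and fraction of
#'   image size.
#' @param illumination Amplitude of the per-sample multiplicative
#'   illumination field (fractional).
#' @param seed Master seed; the whole dataset is a pure function of the
#'   configuration.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_classes = 20L, samples_per_class = 6L,
                         height = 64L, width = 64L,
                         n_veins = c(3L, 8L), thickness = c(1.2, 2.8),
                         contrast = 70, noise_sigma = 8,
                         rotation = 2.5, shift = 0.05,
                         illumination = 0.12, seed = 1L) {
  stopifnot(n_classes >= 1, samples_per_class >= 1, height >= 8, width >= 8,
            length(n_veins) == 2, n_veins[1] >= 1, noise_sigma >= 0)
  structure(list(n_classes = as.integer(n_classes),
                 samples_per_class = as.integer(samples_per_class),
                 height = as.integer(height), width = as.integer(width),
                 n_veins = as.integer(n_veins), thickness = thickness,
                 contrast = contrast, noise_sigma = noise_sigma,
                 rotation = rotation, shift = shift,
                 illumination = illumination, seed = as.integer(seed)),
            class = "synth_config")
}

#' Preset synthetic profiles
#'
#' @param name `"test"` (20 classes x 6 samples at 64 x 64) or `"smoke"`
#'   (100 classes x 6 samples at 96 x 96, the profile of the package's
#'   end-to-end training experiments).
#' @param seed Master seed.
#' @return A [synth_config()].
#' @export
synth_profile <- function(name = c("test", "smoke"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
         test = synth_config(seed = seed),
         smoke = synth_config(n_classes = 100L, height = 96L, width = 96L,
                              seed = seed))
}

derive_seed <- function(seed, a, b = 0L) {
  as.integer((as.numeric(seed) * 48271 + a * 7919 + b * 104729 + 12345) %%
               2147483647)
}

# Smooth curve through random control points, evaluated at every column.
smooth_path <- function(width, height) {
  k <- sample(4:6, 1)
  cx <- sort(stats::runif(k, 1, width))
  cx[1] <- 1; cx[k] <- width
  cy <- stats::runif(k, 0.08 * height, 0.92 * height)
  stats::spline(cx, cy, xout = seq_len(width))$y
}

# Separable Gaussian blur via banded smoothing matrices (edge-renormalized).
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  smoother <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    K <- exp(-d^2 / (2 * sigma^2))
    K[d > ceiling(3 * sigma)] <- 0
    K / rowSums(K)
  }
  smoother(nrow(img)) %*% img %*% t(smoother(ncol(img)))
}

smooth_field <- function(height, width, scale) {
  # low-frequency random surface in [-1, 1]
  g <- matrix(stats::rnorm(scale * scale), scale, scale)
  f <- bilinear_resize(g, height, width)
  f <- gaussian_blur(f, min(height, width) / 12)
  f / max(abs(f), 1e-12)
}

#' Render the vein template of one class
#'
#' Draws `n_veins` smooth dark curves, biased along the horizontal (long
#' finger) axis, on a brighter tissue-like background with a smooth
#' illumination gradient; about half of the veins spawn a short branch. The
#' result is blurred and clipped to `[0, 255]`, and is a pure function of
#' `class_seed`.
#'
#' @param class_seed Integer seed identifying the class.
#' @param config A [synth_config()] (image size, vein count/thickness,
#'   contrast).
#' @return A `height x width` matrix in `[0, 255]`.
#' @export
generate_class_template <- function(class_seed, config = synth_config()) {
  withr::with_seed(as.integer(class_seed), {
    H <- config$height; W <- config$width
    img <- matrix(185, H, W) + 25 * smooth_field(H, W, 3L)
    rows <- matrix(seq_len(H), H, W)
    draw_vein <- function(path, thick, depth) {
      ctr <- matrix(path, H, W, byrow = TRUE)
      img <<- img - depth * exp(-(rows - ctr)^2 / (2 * thick^2))
    }
    nv <- sample(seq(config$n_veins[1], config$n_veins[2]), 1)
    for (v in seq_len(nv)) {
      path <- smooth_path(W, H)
      thick <- stats::runif(1, config$thickness[1], config$thickness[2])
      depth <- config$contrast * stats::runif(1, 0.7, 1)
      draw_vein(path, thick, depth)
      if (stats::runif(1) < 0.5) {   # short branch leaving the main vein
        lo <- sample.int(max(W %/% 2, 1), 1)
        len <- sample(seq(W %/% 4, W %/% 2), 1)
        hi <- min(lo + len, W)
        bp <- rep(NA_real_, W)
        drift <- cumsum(stats::rnorm(hi - lo + 1, 0, 0.8))
        bp[lo:hi] <- path[lo:hi] + drift
        bpath <- ifelse(is.na(bp), path, bp)
        mask <- exp(-((seq_len(W) - (lo + hi) / 2) / (0.6 * (hi - lo + 1)))^2)
        ctr <- matrix(bpath, H, W, byrow = TRUE)
        img <- img - (0.6 * depth) * matrix(mask, H, W, byrow = TRUE) *
          exp(-(rows - ctr)^2 / (2 * (0.7 * thick)^2))
      }
    }
    img <- gaussian_blur(img, 0.8)
    pmin(pmax(img, 0), 255)
  })
}

#' Generate a synthetic vein dataset
#'
#' Per class: one fixed template; per sample: affine jitter (rotation and
#' shift within the configured ranges), a multiplicative illumination field
#' and additive Gaussian noise. The dataset is byte-identical for a fixed
#' configuration (including the master seed).
#'
#' @param config A [synth_config()].
#' @return A [vein_dataset()] with `n_classes * samples_per_class` images.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  images <- vector("list", config$n_classes * config$samples_per_class)
  labels <- integer(length(images))
  i <- 0L
  for (cl in seq_len(config$n_classes)) {
    tmpl <- generate_class_template(derive_seed(config$seed, cl), config)
    for (s in seq_len(config$samples_per_class)) {
      img <- withr::with_seed(derive_seed(config$seed, cl, s), {
        out <- affine_transform(
          tmpl,
          theta = stats::runif(1, -config$rotation, config$rotation),
          shift_r = stats::runif(1, -1, 1) * config$shift * config$height,
          shift_c = stats::runif(1, -1, 1) * config$shift * config$width)
        out <- out * (1 + config$illumination *
                        smooth_field(config$height, config$width, 2L))
        out <- out + stats::rnorm(length(out), 0, config$noise_sigma)
        pmin(pmax(out, 0), 255)
      })
      i <- i + 1L
      images[[i]] <- img
      labels[i] <- cl
    }
  }
  vein_dataset(images, labels,
               class_ids = sprintf("c%03d", seq_len(config$n_classes)))
}

#' Write a dataset to the standard directory layout
#'
#' Creates `dir/<class_id>/<sample>.png` (8-bit grayscale) plus a
#' `manifest.json` describing the generating configuration, in the layout
#' consumed by [load_dataset()].
#'
#' @param dataset A [vein_dataset()].
#' @param dir Output directory (created if missing).
#' @param config Optional [synth_config()] recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, config = NULL) {
  stopifnot(inherits(dataset, "vein_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counter <- integer(dataset$n_classes)
  for (i in seq_along(dataset$images)) {
    cl <- dataset$labels[i]
    cdir <- file.path(dir, dataset$class_ids[cl])
    dir.create(cdir, showWarnings = FALSE)
    counter[cl] <- counter[cl] + 1L
    png::writePNG(dataset$images[[i]] / 255,
                  file.path(cdir, sprintf("s%02d.png", counter[cl])))
  }
  manifest <- list(n_classes = dataset$n_classes,
                   n_images = length(dataset$images),
                   config = if (!is.null(config)) unclass(config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
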