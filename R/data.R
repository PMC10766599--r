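# Dataset container, readers, preprocessing (resize + channel replication)
# and the geometric augmentation policy. Images are grayscale matrices
# (rows x cols) with pixel values in [0, 255] throughout.

#' Construct a vein dataset
#'
#' @param images List of grayscale matrices in `[0, 255]`.
#' @param labels Integer class label per image (contiguous `1..n_classes`
#'   after factoring).
#' @param class_ids Optional character names of the classes.
#' @return An object of class `vein_dataset` with fields `images`, `labels`,
#'   `class_ids`, `n_classes` and `samples_per_class` (`NA` when unbalanced).
#' @export
vein_dataset <- function(images, labels, class_ids = NULL) {
  stopifnot(length(images) == length(labels))
  f <- factor(labels)
  labels <- as.integer(f)
  if (is.null(class_ids)) class_ids <- levels(f)
  counts <- tabulate(labels)
  structure(list(images = images, labels = labels,
                 class_ids = as.character(class_ids),
                 n_classes = nlevels(f),
                 samples_per_class = if (length(unique(counts)) == 1)
                   counts[1] else NA_integer_),
            class = "vein_dataset")
}

#' @export
print.vein_dataset <- function(x, ...) {
  sz <- dim(x$images[[1]])
  cat(sprintf("vein_dataset: %d images, %d classes, %s samples/class, %dx%d\n",
              length(x$images), x$n_classes,
              ifelse(is.na(x$samples_per_class), "unbalanced",
                     x$samples_per_class), sz[1], sz[2]))
  invisible(x)
}

#' Load a dataset from a class-per-directory tree
#'
#' Expects `root/<class_id>/<sample>.<ext>` with PNG, JPEG or TIFF images
#' (BMP is not supported). Classes and samples are ordered
#' lexicographically, so repeated loads give identical ordering. Color
#' images are converted to grayscale by averaging channels.
#'
#' @param root Directory containing one subdirectory per class.
#' @return A [vein_dataset()].
#' @export
load_dataset <- function(root) {
  if (!dir.exists(root)) stop(sprintf("no such directory: %s", root))
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) stop(sprintf("no class directories under %s", root))
  images <- list(); labels <- integer()
  for (ci in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[ci]),
                             pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0)
      stop(sprintf("empty class folder: %s", file.path(root, classes[ci])))
    for (f in files) {
      img <- tryCatch(EBImage::readImage(f),
                      error = function(e)
                        stop(sprintf("cannot read image %s: %s",
                                     f, conditionMessage(e)), call. = FALSE))
      m <- EBImage::imageData(img)
      if (length(dim(m)) == 3) m <- apply(m, c(1, 2), mean)
      # EBImage stores (x, y); transpose to rows = image rows
      images[[length(images) + 1L]] <- t(m) * 255
      labels <- c(labels, ci)
    }
  }
  vein_dataset(images, labels, class_ids = classes)
}

# ---- geometry: bilinear sampling with edge replication ----

# Sample img (H x W) at real-valued (row, col) coordinate grids of equal
# dims; coordinates are clamped, so borders replicate edge pixels.
bilinear_sample <- function(img, rows, cols) {
  H <- nrow(img); W <- ncol(img)
  rows <- pmin(pmax(rows, 1), H)
  cols <- pmin(pmax(cols, 1), W)
  r0 <- pmin(floor(rows), H - 1L); c0 <- pmin(floor(cols), W - 1L)
  if (H == 1) r0[] <- 1
  if (W == 1) c0[] <- 1
  fr <- rows - r0; fc <- cols - c0
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  v00 <- img[cbind(as.vector(r0), as.vector(c0))]
  v01 <- img[cbind(as.vector(r0), as.vector(c1))]
  v10 <- img[cbind(as.vector(r1), as.vector(c0))]
  v11 <- img[cbind(as.vector(r1), as.vector(c1))]
  out <- (1 - fr) * (1 - fc) * v00 + (1 - fr) * fc * v01 +
    fr * (1 - fc) * v10 + fr * fc * v11
  matrix(out, nrow = nrow(rows))
}

bilinear_resize <- function(img, out_h, out_w) {
  if (nrow(img) == out_h && ncol(img) == out_w) return(img)
  sr <- nrow(img) / out_h
  sc <- ncol(img) / out_w
  rows <- matrix((seq_len(out_h) - 0.5) * sr + 0.5, out_h, out_w)
  cols <- matrix((seq_len(out_w) - 0.5) * sc + 0.5, out_h, out_w,
                 byrow = TRUE)
  bilinear_sample(img, rows, cols)
}

# Apply a forward affine map (about the image center) to an image by inverse
# bilinear sampling. theta in degrees; shifts in pixels; shear is the
# horizontal-shear coefficient; zoom > 1 magnifies; flips mirror the image.
affine_transform <- function(img, theta = 0, shift_r = 0, shift_c = 0,
                             shear = 0, zoom = 1, vflip = FALSE,
                             hflip = FALSE) {
  H <- nrow(img); W <- ncol(img)
  a <- theta * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  Sh <- matrix(c(1, 0, shear, 1), 2)
  Fp <- diag(c(if (vflip) -1 else 1, if (hflip) -1 else 1))
  A <- zoom * R %*% Sh %*% Fp              # forward map (row, col)
  Ai <- solve(A)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rg <- matrix(seq_len(H), H, W) - cy - shift_r
  cg <- matrix(seq_len(W), H, W, byrow = TRUE) - cx - shift_c
  rows <- Ai[1, 1] * rg + Ai[1, 2] * cg + cy
  cols <- Ai[2, 1] * rg + Ai[2, 2] * cg + cx
  bilinear_sample(img, rows, cols)
}

#' Augmentation policy
#'
#' The default values reproduce the standard geometric policy for finger-vein
#' training: random vertical flip (probability 0.5), no horizontal flip,
#' rotation within +/- 2.5 degrees, width/height shifts within +/- 5% of each
#' dimension, shear within +/- 0.05 and zoom in `[0.95, 1.05]`. Augmentation
#' transforms samples in place each epoch; the training set never grows.
#'
#' @param vertical_flip,horizontal_flip Enable random flips (probability 0.5
#'   when enabled).
#' @param rotation Degree range for random rotation (`+/- rotation`).
#' @param width_shift,height_shift Shift ranges as fractions of image size.
#' @param shear Shear-coefficient range.
#' @param zoom Zoom range half-width (zoom drawn from `[1 - zoom, 1 + zoom]`).
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(vertical_flip = TRUE, horizontal_flip = FALSE,
                           rotation = 2.5, width_shift = 0.05,
                           height_shift = 0.05, shear = 0.05, zoom = 0.05) {
  structure(list(vertical_flip = vertical_flip,
                 horizontal_flip = horizontal_flip,
                 rotation = rotation, width_shift = width_shift,
                 height_shift = height_shift, shear = shear, zoom = zoom),
            class = "augment_config")
}

#' Randomly augment one image
#'
#' Draws one transform from the policy (uniformly within each symmetric
#' range) and applies it with bilinear resampling; exposed borders replicate
#' edge pixels. Output shape equals input shape.
#'
#' @param image Grayscale matrix.
#' @param config An [augment_config()].
#' @param seed Optional seed for a reproducible draw; by default the current
#'   RNG state is used (seed it once per run).
#' @return The transformed image.
#' @export
augment <- function(image, config = augment_config(), seed = NULL) {
  stopifnot(inherits(config, "augment_config"))
  draw <- function() {
    u <- stats::runif(7)
    list(theta = (2 * u[1] - 1) * config$rotation,
         shift_r = (2 * u[2] - 1) * config$height_shift * nrow(image),
         shift_c = (2 * u[3] - 1) * config$width_shift * ncol(image),
         shear = (2 * u[4] - 1) * config$shear,
         zoom = 1 + (2 * u[5] - 1) * config$zoom,
         vflip = config$vertical_flip && u[6] < 0.5,
         hflip = config$horizontal_flip && u[7] < 0.5)
  }
  pars <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (pars$theta == 0 && pars$shift_r == 0 && pars$shift_c == 0 &&
      pars$shear == 0 && pars$zoom == 1 && !pars$vflip && !pars$hflip)
    return(image)
  affine_transform(image, pars$theta, pars$shift_r, pars$shift_c,
                   pars$shear, pars$zoom, pars$vflip, pars$hflip)
}

#' Preprocess an image for the network
#'
#' Bilinear resize to `size x size`, replication of the single gray channel
#' to 3 identical channels, and scaling to `[0, 1]`.
#'
#' @param image Grayscale matrix in `[0, 255]`.
#' @param size Target spatial size (224 by default).
#' @return A `(size, size, 3)` array in `[0, 1]`.
#' @export
preprocess <- function(image, size = 224L) {
  r <- bilinear_resize(image, size, size) / 255
  array(r, dim = c(size, size, 3))
}

preprocess_batch <- function(images, size) {
  out <- array(0, dim = c(size, size, 3, length(images)))
  for (i in seq_along(images)) out[, , , i] <- preprocess(images[[i]], size)
  out
}

#' Class-balanced batch sampler
#'
#' Composes batches of `classes_per_batch` distinct classes with
#' `samples_per_class` samples each (the 32 x 4 = 128 recipe by default).
#' Classes are covered at least once per epoch where feasible; classes with
#' fewer than `samples_per_class` samples are sampled with replacement.
#'
#' @param dataset A [vein_dataset()] (or integer label vector).
#' @param classes_per_batch,samples_per_class Batch composition.
#' @return A list of integer index vectors, one per batch, each of length
#'   `classes_per_batch * samples_per_class`.
#' @export
balanced_batch_sampler <- function(dataset, classes_per_batch = 32L,
                                   samples_per_class = 4L) {
  labels <- if (inherits(dataset, "vein_dataset")) dataset$labels else dataset
  by_class <- split(seq_along(labels), labels)
  nc <- length(by_class)
  if (nc < classes_per_batch)
    stop(sprintf("need at least %d classes, have %d", classes_per_batch, nc))
  order_cl <- sample.int(nc)
  n_batches <- ceiling(nc / classes_per_batch)
  batches <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    lo <- (b - 1L) * classes_per_batch + 1L
    cl <- order_cl[lo:min(lo + classes_per_batch - 1L, nc)]
    if (length(cl) < classes_per_batch)   # pad last batch with other classes
      cl <- c(cl, sample(setdiff(order_cl, cl),
                         classes_per_batch - length(cl)))
    batches[[b]] <- unlist(lapply(cl, function(ci) {
      idx <- by_class[[ci]]
      if (length(idx) >= samples_per_class) sample(idx, samples_per_class)
      else sample(idx, samples_per_class, replace = TRUE)
    }), use.names = FALSE)
  }
  batches
}
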