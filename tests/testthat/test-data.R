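test_that("datasets load from a class-per-directory tree deterministically", {
  root <- withr::local_tempdir()
  set.seed(50)
  for (cl in c("f1", "f2", "f3")) {
    dir.create(file.path(root, cl))
    for (s in 1:2)
      png::writePNG(matrix(runif(64), 8),
                    file.path(root, cl, sprintf("s%d.png", s)))
  }
  ds <- load_dataset(root)
  expect_s3_class(ds, "vein_dataset")
  expect_equal(ds$n_classes, 3)
  expect_equal(ds$samples_per_class, 2)
  expect_equal(ds$class_ids, c("f1", "f2", "f3"))
  ds2 <- load_dataset(root)
  expect_identical(ds$images, ds2$images)
  expect_identical(ds$labels, ds2$labels)
  expect_true(all(vapply(ds$images, max, 0) <= 255))
})

test_that("loader errors name the offending folder or file", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "empty_class"))
  expect_error(load_dataset(root), "empty_class")
  writeLines("not a png", file.path(root, "empty_class", "bad.png"))
  expect_error(load_dataset(root), "bad.png")
  expect_error(load_dataset(file.path(root, "missing")), "no such directory")
})

test_that("preprocess resizes, replicates channels and rescales", {
  set.seed(51)
  img <- matrix(runif(100 * 300, 0, 255), 100)   # ROI-like aspect
  x <- preprocess(img, size = 224L)
  expect_equal(dim(x), c(224, 224, 3))
  expect_identical(x[, , 1], x[, , 2])
  expect_identical(x[, , 1], x[, , 3])
  expect_true(all(x >= 0 & x <= 1))
  # constant image maps to the constant value / 255
  xc <- preprocess(matrix(128, 40, 60), size = 32L)
  expect_equal(as.vector(xc), rep(128 / 255, 32 * 32 * 3), tolerance = 1e-12)
  # already-sized input is passed through untouched
  sq <- matrix(runif(32 * 32, 0, 255), 32)
  expect_equal(preprocess(sq, 32L)[, , 1], sq / 255, tolerance = 1e-12)
})

test_that("augmentation with zero ranges is the identity", {
  img <- matrix(runif(64 * 48, 0, 255), 64)
  cfg <- augment_config(vertical_flip = FALSE, horizontal_flip = FALSE,
                        rotation = 0, width_shift = 0, height_shift = 0,
                        shear = 0, zoom = 0)
  expect_identical(augment(img, cfg), img)
})

test_that("augmentation is seeded-reproducible and shape-preserving", {
  set.seed(52)
  img <- matrix(runif(40 * 50, 0, 255), 40)
  a1 <- augment(img, seed = 99L)
  a2 <- augment(img, seed = 99L)
  expect_identical(a1, a2)
  expect_equal(dim(a1), dim(img))
})

test_that("vertical flips occur about half the time and horizontal never", {
  # marker image: bright top-left corner breaks both symmetries
  img <- matrix(0, 9, 9); img[1:2, 1:2] <- 255
  cfg <- augment_config(rotation = 0, width_shift = 0, height_shift = 0,
                        shear = 0, zoom = 0)
  flips <- withr::with_seed(53, {
    vapply(1:1000, function(i) {
      a <- augment(img, cfg)
      if (a[9, 1] > 100) "v" else if (a[1, 9] > 100) "h" else "id"
    }, character(1))
  })
  expect_equal(sum(flips == "h"), 0)
  expect_gt(mean(flips == "v"), 0.45)
  expect_lt(mean(flips == "v"), 0.55)
})

test_that("augmented borders replicate edges rather than fill with a constant", {
  img <- matrix(200, 20, 20)
  cfg <- augment_config(vertical_flip = FALSE, rotation = 0, shear = 0,
                        zoom = 0, width_shift = 0.3, height_shift = 0)
  a <- augment(img, cfg, seed = 3L)
  expect_true(all(a == 200))   # shifting a constant image changes nothing
})

test_that("balanced batches have the configured composition", {
  labels <- rep(1:64, each = 6)
  withr::with_seed(54, {
    batches <- balanced_batch_sampler(labels, 32L, 4L)
    for (b in batches) {
      expect_length(b, 128)
      expect_equal(length(unique(labels[b])), 32)
      expect_true(all(table(labels[b]) == 4))
    }
    # each class appears at least once over the epoch
    expect_setequal(unique(labels[unlist(batches)]), 1:64)
  })
  small <- balanced_batch_sampler(rep(1:8, each = 6), 8L, 4L)
  expect_length(small[[1]], 32)
  expect_equal(length(unique(rep(1:8, each = 6)[small[[1]]])), 8)
  expect_error(balanced_batch_sampler(rep(1:4, each = 6), 8L, 4L),
               "at least 8 classes")
})

test_that("the sampler is reproducible under a fixed seed", {
  labels <- rep(1:40, each = 5)
  b1 <- withr::with_seed(55, balanced_batch_sampler(labels, 16L, 4L))
  b2 <- withr::with_seed(55, balanced_batch_sampler(labels, 16L, 4L))
  expect_identical(b1, b2)
})

test_that("classes with too few samples are sampled with replacement", {
  labels <- rep(1:10, each = 2)
  b <- withr::with_seed(56, balanced_batch_sampler(labels, 10L, 4L))
  expect_length(b[[1]], 40)
  expect_true(all(table(labels[b[[1]]]) == 4))
})
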