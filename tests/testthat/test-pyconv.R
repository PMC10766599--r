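test_that("pyconv_spec validates its invariants", {
  s <- pyconv_spec(64)
  expect_s3_class(s, "pyconv_spec")
  expect_equal(s$kernel_sizes, c(3L, 5L, 7L, 9L))
  expect_equal(s$out_channels, rep(16L, 4))
  expect_error(pyconv_spec(64, c(3, 5, 5, 9)), "strictly increase")
  expect_error(pyconv_spec(64, c(3, 4)), "odd")
  # groups must divide both channel counts, error names the level
  expect_error(pyconv_spec(62, c(3, 5, 7, 9), rep(16, 4), c(1, 4, 8, 16)),
               "level 2")
})

test_that("single-level pyconv reduces to a standard convolution", {
  set.seed(1)
  layer <- build_pyconv(pyconv_spec(4L, 3L, 8L, 1L))
  x <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  y <- pyconv_apply(layer, x)
  expect_equal(dim(y), c(8L, 8L, 8L))
  # equality with a plain same-padded 3x3 convolution evaluated by loops
  w <- layer$weights[[1]]
  ref <- array(0, c(8, 8, 8))
  xp <- array(0, c(4, 10, 10)); xp[, 2:9, 2:9] <- x
  for (oc in 1:8) for (h in 1:8) for (wd in 1:8) {
    acc <- 0
    for (c in 1:4) for (kh in 1:3) for (kw in 1:3)
      acc <- acc + xp[c, h + kh - 1, wd + kw - 1] * w[kh, kw, c, oc]
    ref[oc, h, wd] <- acc
  }
  expect_equal(y, ref, tolerance = 1e-5)
})

test_that("default 4-level pyconv preserves spatial size and sums channels", {
  set.seed(2)
  layer <- build_pyconv(pyconv_spec(64L))
  x <- array(rnorm(64 * 16 * 16), c(64, 16, 16))
  y <- pyconv_apply(layer, x)
  expect_equal(dim(y), c(64L, 16L, 16L))
  # zero kernels give a zero map of the same shape (linearity)
  zero <- layer
  zero$weights <- lapply(zero$weights, function(w) w * 0)
  expect_true(all(pyconv_apply(zero, x) == 0))
})

test_that("pyconv output is reproducible across calls", {
  set.seed(3)
  layer <- build_pyconv(pyconv_spec(16L, out_channels = rep(8L, 4),
                                    groups = c(1L, 2L, 4L, 8L)))
  x <- array(rnorm(16 * 6 * 6), c(16, 6, 6))
  expect_identical(pyconv_apply(layer, x), pyconv_apply(layer, x))
})

test_that("idealized parameter count collapses to K1^2 * FMi * FMoi per level", {
  p <- pyconv_param_count(64, c(3, 5, 7, 9), rep(16, 4))
  expect_equal(p$per_level, rep(9 * 64 * 16, 4))
  expect_equal(p$total, 36864)
  # equals one standard 3x3 convolution 64 -> 64
  expect_equal(p$total, 9 * 64 * 64)
  # degenerate single-level form
  p1 <- pyconv_param_count(64, 3, 64)
  expect_equal(p1$total, 36864)
  # linear in the output channels
  p2 <- pyconv_param_count(64, c(3, 5, 7, 9), rep(32, 4))
  expect_equal(p2$total, 2 * p$total)
  expect_error(pyconv_param_count(0, 3, 8), "positive")
})

test_that("FLOP count is the parameter count times the map area, termwise", {
  p <- pyconv_param_count(64, c(3, 5, 7, 9), rep(16, 4))
  f1 <- pyconv_flop_count(64, c(3, 5, 7, 9), rep(16, 4), 1, 1)
  expect_equal(f1$per_level, p$per_level)
  f <- pyconv_flop_count(64, c(3, 5, 7, 9), rep(16, 4), 16, 16)
  expect_equal(f$per_level, p$per_level * 256)
  expect_equal(f$total, 9437184)
  # pyramid total equals one K1^2 standard conv with FMo = sum(FMoi)
  expect_equal(f$total, 9 * 64 * 64 * 256)
})

test_that("parameter-equality holds over a randomized configuration grid", {
  set.seed(42)
  for (i in 1:120) {
    fmi <- sample(16:256, 1)
    fmo <- sample(4:64, 4, replace = TRUE)
    p <- pyconv_param_count(fmi, c(3, 5, 7, 9), fmo)
    expect_equal(p$per_level, 9 * fmi * fmo)
    hw <- sample(1:32, 2)
    f <- pyconv_flop_count(fmi, c(3, 5, 7, 9), fmo, hw[1], hw[2])
    expect_equal(f$per_level, p$per_level * hw[1] * hw[2])
  }
})

test_that("realized count matches the idealized one when groups equal K^2 ratios", {
  # K = (3, 9): ratio 81/9 = 9 is an integer, so groups (1, 9) realize the
  # idealized depth schedule exactly
  s <- pyconv_spec(18L, c(3L, 9L), c(9L, 9L), c(1L, 9L))
  ideal <- pyconv_param_count(18, c(3, 9), c(9, 9))
  real <- pyconv_realized_params(s)
  expect_equal(real$per_level, ideal$per_level)
  expect_equal(real$total, ideal$total)
  # with the practical (1, 4, 8, 16) schedule the counts differ and both
  # are reported
  s4 <- pyconv_spec(64L)
  expect_false(pyconv_realized_params(s4)$total ==
                 pyconv_param_count(64, c(3, 5, 7, 9), rep(16, 4))$total)
})
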