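test_that("open-set splits are disjoint, exhaustive halves and seeded", {
  cls <- sprintf("f%02d", 1:100)
  folds <- split_open_set(cls, 1:4)
  for (f in folds) {
    expect_length(f$train, 50)
    expect_length(f$test, 50)
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), cls)
  }
  expect_identical(split_open_set(cls, 7L), split_open_set(cls, 7L))
  # distinct seeds give distinct partitions (pinned seeds, 20 classes)
  f20 <- split_open_set(1:20, 1:4)
  expect_gte(length(unique(lapply(f20, `[[`, "train"))), 2)
  expect_error(split_open_set("a"), "2 classes")
})

test_that("pair counts follow the N_g and N_i formulas on balanced sets", {
  p <- make_pairs(rep(1:2, each = 2))
  expect_equal(p$n_genuine, 2)
  expect_equal(p$n_impostor, 1)
  p <- make_pairs(rep(1:10, each = 6))
  expect_equal(p$n_genuine, 150)     # 10 * 6*5/2
  expect_equal(p$n_impostor, 45)     # choose(10, 2)
  expect_equal(make_pairs(rep(1, 4))$n_impostor, 0)
})

test_that("pair counts match exhaustive enumeration for all small shapes", {
  for (nc in c(2, 5, 9, 12)) {
    for (nf in c(2, 3, 6, 8)) {
      labels <- rep(seq_len(nc), each = nf)
      p <- make_pairs(labels)
      expect_equal(p$n_genuine, nc * nf * (nf - 1) / 2)
      expect_equal(p$n_impostor, choose(nc, 2))
      # genuine pairs are same-class, impostor pairs cross-class
      expect_true(all(labels[p$genuine[, 1]] == labels[p$genuine[, 2]]))
      expect_true(all(labels[p$impostor[, 1]] != labels[p$impostor[, 2]]))
      # every unordered class pair appears exactly once
      cp <- paste(labels[p$impostor[, 1]], labels[p$impostor[, 2]])
      expect_equal(length(unique(cp)), choose(nc, 2))
    }
  }
})

test_that("unbalanced classes use per-class pair counts", {
  labels <- c(1, 1, 1, 2, 2, 3)
  p <- make_pairs(labels)
  expect_equal(p$n_genuine, 3 + 1 + 0)
  expect_equal(p$n_impostor, 3)
})

test_that("exhaustive impostor mode enumerates all cross pairs", {
  p <- make_pairs(rep(1:3, each = 2), impostor = "exhaustive")
  expect_equal(p$n_impostor, choose(3, 2) * 4)
})

test_that("FAR and FRR behave correctly at extreme thresholds", {
  ps <- pair_set(genuine = c(0.9, 0.8), impostor = c(0.4, 0.6))
  cv <- compute_far_frr(ps, thresholds = c(-1, 0.7, 2))
  expect_equal(cv$far, c(1, 0, 0))
  expect_equal(cv$frr, c(0, 0, 1))
  expect_error(compute_far_frr(pair_set(numeric(), 1)), "at least one")
})

test_that("FAR is non-increasing and FRR non-decreasing in the threshold", {
  set.seed(40)
  for (i in 1:20) {
    ps <- pair_set(rnorm(30, 1), rnorm(30))
    cv <- compute_far_frr(ps)
    expect_true(all(diff(cv$far) <= 0))
    expect_true(all(diff(cv$frr) >= 0))
  }
})

test_that("perfectly separated scores give EER 0 and accuracy 1", {
  ps <- pair_set(genuine = c(0.8, 0.9, 0.95), impostor = c(0.1, 0.2))
  expect_equal(compute_eer(ps)$eer, 0)
  expect_equal(compute_accuracy(ps), 1)
})

test_that("EER matches the exhaustive sweep oracle on random score sets", {
  set.seed(41)
  for (i in 1:100) {
    ng <- sample(3:25, 1); ni <- sample(3:25, 1)
    sep <- runif(1, 0, 2)
    ps <- pair_set(rnorm(ng, sep), rnorm(ni))
    expect_equal(compute_eer(ps)$eer, oracle_eer(ps$genuine, ps$impostor),
                 tolerance = 1e-9)
  }
})

test_that("identically distributed scores give EER near one half", {
  set.seed(42)
  ps <- pair_set(rnorm(1e4), rnorm(1e4))
  expect_equal(compute_eer(ps)$eer, 0.5, tolerance = 0.02)
})

test_that("accuracy matches the exhaustive sweep oracle", {
  set.seed(43)
  for (i in 1:50) {
    ps <- pair_set(rnorm(12, 1), rnorm(12))
    expect_equal(compute_accuracy(ps), oracle_accuracy(ps$genuine, ps$impostor),
                 tolerance = 1e-12)
  }
  # degenerate: all scores equal -> majority class rate
  ps <- pair_set(rep(0.5, 3), rep(0.5, 7))
  expect_equal(compute_accuracy(ps), 0.7)
})

test_that("verification_result assembles curves and summary metrics", {
  ps <- pair_set(c(0.9, 0.8, 0.6), c(0.3, 0.55, 0.1))
  vr <- verification_result(ps)
  expect_s3_class(vr, "verification_result")
  expect_equal(vr$n_genuine, 3)
  expect_equal(vr$n_impostor, 3)
  expect_true(vr$eer >= 0 && vr$eer <= 1)
  expect_true(vr$acc >= 0.5 && vr$acc <= 1)
  expect_s3_class(ggplot2::autoplot(vr), "ggplot")
})

test_that("cosine and euclidean scoring rank a matched pair above a mismatch", {
  emb <- rbind(c(1, 0), c(0.99, 0.1), c(-1, 0.2))
  emb <- emb / sqrt(rowSums(emb^2))
  pr <- list(genuine = rbind(c(1L, 2L)), impostor = rbind(c(1L, 3L)))
  for (metric in c("cosine", "euclidean")) {
    ps <- score_pairs(emb, pr, metric)
    expect_gt(ps$genuine, ps$impostor)
  }
})
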