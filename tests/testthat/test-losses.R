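test_that("center loss matches hand-computed values on toy batches", {
  st <- center_state(3, 2)
  # batch 1: one sample at (1, 0), center at origin: 0.5 * 1 = 0.5
  expect_equal(center_loss(matrix(c(1, 0), 1), 1L, st), 0.5)
  # batch 2: two samples, centers moved
  st$centers[1, ] <- c(1, 1); st$centers[2, ] <- c(-1, 0)
  x <- rbind(c(2, 1), c(-1, 2))
  # 0.5 * (|x1 - c1|^2 + |x2 - c2|^2) = 0.5 * (1 + 4) = 2.5
  expect_equal(center_loss(x, c(1L, 2L), st), 2.5)
  # batch 3: samples exactly on their centers
  expect_equal(center_loss(st$centers[c(1, 2), ], c(1L, 2L), st), 0)
})

test_that("center loss is additive over samples", {
  set.seed(30)
  st <- center_state(4, 5)
  st$centers[] <- rnorm(20)
  x <- matrix(rnorm(15), 3)
  y <- c(2L, 4L, 1L)
  l1 <- center_loss(x, y, st)
  expect_equal(center_loss(rbind(x, x), c(y, y), st), 2 * l1)
  expect_gte(l1, 0)
})

test_that("unseen labels are rejected by name", {
  st <- center_state(2, 2)
  expect_error(center_loss(matrix(0, 1, 2), 5L, st), "label 5")
})

test_that("moving an embedding toward its center decreases the loss", {
  set.seed(31)
  st <- center_state(1, 3)
  st$centers[1, ] <- c(1, 2, 3)
  x0 <- c(4, -1, 0)
  losses <- vapply(seq(0, 0.9, by = 0.1), function(a) {
    center_loss(matrix(x0 + a * (st$centers[1, ] - x0), 1), 1L, st)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("center updates initialize at first sight then move toward batch means", {
  st <- center_state(2, 2, center_lr = 0.5)
  x <- rbind(c(2, 0), c(4, 2), c(-2, -2))
  st2 <- update_centers(st, x, c(1L, 1L, 2L))
  # first sight: centers jump to the batch class means
  expect_equal(st2$centers[1, ], c(3, 1))
  expect_equal(st2$centers[2, ], c(-2, -2))
  # subsequent updates are exponential-moving with rate 0.5
  st3 <- update_centers(st2, rbind(c(5, 3)), 1L)
  expect_equal(st3$centers[1, ], c(4, 2))
})

test_that("lambda = 0 reduces the joint loss to plain cross-entropy", {
  set.seed(32)
  logits <- matrix(rnorm(12), 3)
  emb <- matrix(rnorm(6), 3)
  y <- c(1L, 4L, 2L)
  st <- center_state(4, 2)
  jl <- joint_loss(logits, emb, y, st, loss_config(lambda = 0))
  expect_equal(jl$loss, veinnet:::softmax_xent(logits, y)$loss)
})

test_that("uniform logits give cross-entropy ln K exactly", {
  for (K in c(2, 5, 17)) {
    logits <- matrix(0, 4, K)
    ce <- veinnet:::softmax_xent(logits, sample.int(K, 4, replace = TRUE))
    expect_equal(ce$loss, log(K), tolerance = 1e-12)
  }
})

test_that("joint loss composes its two terms with the configured weight", {
  set.seed(33)
  logits <- rbind(c(2, -1, 0.5), c(0, 0, 3))
  emb <- rbind(c(1, 0), c(0, 2))
  y <- c(1L, 3L)
  st <- center_state(3, 2)
  st$centers[1, ] <- c(0.5, 0); st$centers[3, ] <- c(0, 1)
  # scalar evaluation of both terms
  ls <- mean(c(-log(exp(2) / sum(exp(c(2, -1, 0.5)))),
               -log(exp(3) / sum(exp(c(0, 0, 3))))))
  lc <- 0.5 * (0.25 + 1)
  jl <- joint_loss(logits, emb, y, st, loss_config(lambda = 0.1))
  expect_equal(jl$softmax, ls, tolerance = 1e-12)
  expect_equal(jl$center, lc, tolerance = 1e-12)
  expect_equal(jl$loss, ls + 0.1 * lc, tolerance = 1e-12)
})

test_that("cross-entropy gradients match finite differences", {
  set.seed(34)
  logits <- matrix(rnorm(8), 2)
  y <- c(3L, 1L)
  g <- veinnet:::softmax_xent(logits, y)$grad
  for (k in 1:8) {
    le <- logits; le[k] <- le[k] + 1e-6
    up <- veinnet:::softmax_xent(le, y)$loss
    le[k] <- le[k] - 2e-6
    dn <- veinnet:::softmax_xent(le, y)$loss
    expect_equal(g[k], (up - dn) / 2e-6, tolerance = 1e-6)
  }
})

test_that("training with the center term shrinks intra-class spread", {
  # direct optimization of free 2-D embeddings with a linear softmax head:
  # the joint objective pulls same-class points together, plain softmax
  # only separates classes
  set.seed(35)
  n_per <- 10
  y <- rep(1:2, each = n_per)
  run <- function(lambda) {
    x <- matrix(rnorm(40, sd = 2), 20)
    w <- matrix(0.1, 2, 2)
    st <- center_state(2, 2, center_lr = 0.5)
    for (it in 1:200) {
      logits <- x %*% w
      ce <- veinnet:::softmax_xent(logits, y)
      dx <- ce$grad %*% t(w) + lambda * veinnet:::center_loss_grad(x, y, st)
      dw <- t(x) %*% ce$grad
      x <- x - 0.1 * dx
      w <- w - 0.1 * dw
      st <- update_centers(st, x, y)
    }
    mean(vapply(1:2, function(cl) {
      xs <- x[y == cl, ]
      mean(sqrt(rowSums(sweep(xs, 2, colMeans(xs))^2)))
    }, numeric(1)))
  }
  spread_joint <- run(0.5)
  spread_plain <- run(0)
  expect_lt(spread_joint, spread_plain)
})
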