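# two well-separated Gaussian blobs in d dimensions; class 0 centered at
# the origin, class 1 at distance 6 sigma
make_blobs <- function(n = 2000, d = 4, sep = 6, seed = 7) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * d), n)
  x[y == 1, ] <- x[y == 1, ] + sep / sqrt(d)
  list(x = x, y = y)
}

test_that("separable blobs are classified almost perfectly", {
  b <- make_blobs()
  m <- train_svm(b$x, b$y, seed = 7)
  expect_gte(m$train_accuracy, 99)
  p <- predict_proba(m, b$x)
  expect_true(all(p >= 0 & p <= 1))
  # a probe deep inside the class-0 (low BV) cloud
  expect_gt(predict_proba(m, matrix(0, 1, 4)), 0.9)
  # the midpoint between the two symmetric centroids is ambiguous
  mid <- matrix(rep(3 / sqrt(4), 4), 1)
  p_mid <- predict_proba(m, mid)
  expect_gte(p_mid, 0.4); expect_lte(p_mid, 0.6)
})

test_that("permuted labels give chance-level held-out accuracy", {
  b <- make_blobs(n = 2000)
  set.seed(7)
  y_perm <- sample(b$y)
  tr <- 1:1000; te <- 1001:2000
  m <- train_svm(b$x[tr, ], y_perm[tr], seed = 7)
  acc <- voxel_accuracy(assign_labels(predict_proba(m, b$x[te, ])),
                        y_perm[te])
  expect_gte(acc, 47); expect_lte(acc, 53)
})

test_that("training is deterministic for a fixed seed", {
  b <- make_blobs(n = 600)
  probe <- matrix(rnorm(40), 10)
  m1 <- train_svm(b$x, b$y, seed = 3)
  m2 <- train_svm(b$x, b$y, seed = 3)
  expect_identical(predict_proba(m1, probe), predict_proba(m2, probe))
})

test_that("degenerate labels and dimension mismatches are rejected", {
  b <- make_blobs(n = 200)
  expect_error(train_svm(b$x, rep(0L, 200)), "degenerate-labels")
  m <- train_svm(b$x, b$y, seed = 1)
  expect_error(predict_proba(m, matrix(0, 1, 3)), "dimension")
})

test_that("stratified capping limits the per-class training size", {
  b <- make_blobs(n = 2000)
  m <- train_svm(b$x, b$y, seed = 1, per_class_cap = 100L)
  expect_identical(m$n_train, 200L)
  expect_gte(m$train_accuracy, 99)
})

test_that("predictions are invariant to affine rescaling of a feature", {
  b <- make_blobs(n = 600)
  probe <- matrix(rnorm(40), 10)
  m1 <- train_svm(b$x, b$y, seed = 3)
  x2 <- b$x; x2[, 2] <- 10 * x2[, 2] + 5
  m2 <- train_svm(x2, b$y, seed = 3)
  probe2 <- probe; probe2[, 2] <- 10 * probe2[, 2] + 5
  expect_equal(predict_proba(m1, probe), predict_proba(m2, probe2),
               tolerance = 1e-8)
})

test_that("label assignment uses a strict threshold and is monotone", {
  expect_identical(assign_labels(c(0, 0.5, 0.500001, 1)), c(1L, 1L, 0L, 0L))
  set.seed(8)
  p <- runif(200)
  n_lbv <- vapply(seq(0, 1, by = 0.1), function(th) {
    sum(assign_labels(p, th) == 0L)
  }, numeric(1))
  expect_true(all(diff(n_lbv) <= 0))
  expect_error(assign_labels(c(-0.1, 0.5)), "probabilities")
})

test_that("glance summarizes a trained classifier", {
  b <- make_blobs(n = 400)
  g <- glance(train_svm(b$x, b$y, seed = 2))
  expect_identical(g$C, 200)
  expect_identical(g$gamma, 0.2)
  expect_identical(g$n_train, 400L)
})
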