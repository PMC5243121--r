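test_that("single-feature merit is the absolute feature-class correlation", {
  set.seed(5)
  y <- rep(c(0, 1), each = 100)
  x <- cbind(rnorm(200) + y, rnorm(200))
  expect_equal(cfs_merit(1, x, y), abs(cor(x[, 1], y)))
  expect_equal(cfs_merit(2, x, y), abs(cor(x[, 2], y)))
  expect_error(cfs_merit(1, x, rep(1, 200)), "two classes")
})

test_that("exact duplicates of a feature give no merit gain", {
  # k identical copies score exactly the singleton merit:
  # k*r / sqrt(k + k(k-1)*1) = r, so redundancy can never be mistaken for
  # new information
  set.seed(6)
  y <- rep(c(0, 1), each = 150)
  for (i in 1:10) {
    f <- rnorm(300) + runif(1, 0, 2) * y
    x <- cbind(f, f, f, f)
    m1 <- cfs_merit(1, x, y)
    for (k in 2:4) {
      expect_equal(cfs_merit(seq_len(k), x, y), m1, tolerance = 1e-10)
    }
  }
})

test_that("zero-variance features contribute zero correlation", {
  y <- rep(c(0, 1), each = 20)
  x <- cbind(rep(2, 40), rnorm(40) + y)
  expect_equal(cfs_merit(1, x, y), 0)
  expect_gt(cfs_merit(2, x, y), 0)
})

test_that("searches find a planted signal feature among noise", {
  set.seed(123)
  n <- 2000
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 10), n)
  x[, 4] <- y + 0.01 * rnorm(n)    # near-perfect signal feature
  bf <- best_first_search(x, y)
  gr <- greedy_forward_search(x, y)
  expect_true(4 %in% bf$indices)
  expect_true(4 %in% gr$indices)
  # determinism on an identical matrix
  expect_identical(bf$indices, best_first_search(x, y)$indices)
  expect_identical(gr$indices, greedy_forward_search(x, y)$indices)
})

test_that("pure-noise features yield only a weak merit", {
  set.seed(124)
  n <- 2000
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 10), n)
  expect_lt(best_first_search(x, y)$merit, 0.2)
  expect_lt(greedy_forward_search(x, y)$merit, 0.2)
})

test_that("phantom Haar selection favors global-shape coefficients", {
  # at the realistic noise level the class signal concentrates in the
  # approximation/coarse-detail coefficients (global curve shape), so at
  # least half of the selected indices fall in the A5/D5-D3 range (<= 8)
  ph <- phantom_fix(noise = 0.05)
  aif <- extract_aif(ph$series, ph$artery_mask, baseline_frames = 10)
  win <- preprocess_series(ph$series, ph$tumor_mask, aif)
  co <- haar_full(win$window)
  y <- ph$truth$label[win$voxel]
  sel <- best_first_search(co, y)
  expect_gte(mean(sel$indices <= 8), 0.5)
})

test_that("top-PC selection returns the leading indices and validates k", {
  set.seed(9)
  b <- fit_pca(matrix(rnorm(64 * 32), 64))
  expect_identical(select_top_pcs(b, 4), 1:4)
  expect_identical(select_top_pcs(b, 32), 1:32)
  expect_error(select_top_pcs(b, 0), "between 1 and")
  expect_error(select_top_pcs(b, 33), "between 1 and")
})
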