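test_that("Haar transform annihilates constants and counts coefficients", {
  co <- haar_full(rep(3.5, 32))
  expect_length(co, 32)                       # 1 approximation + 31 details
  expect_equal(unname(co[1]), 3.5)
  expect_equal(unname(co[-1]), rep(0, 31))
  expect_identical(names(co)[1:4], c("A5", "D5", "D4.1", "D4.2"))
  expect_error(haar_full(rnorm(30)), "non-dyadic")
})

test_that("Haar transform is linear", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(32); y <- rnorm(32)
    a <- runif(1, -3, 3); b <- runif(1, -3, 3)
    expect_equal(haar_full(a * x + b * y),
                 a * haar_full(x) + b * haar_full(y), tolerance = 1e-10)
  }
})

test_that("inverse transform reconstructs exactly in both conventions", {
  expect_equal(haar_inverse(rep(0, 32)), rep(0, 32))
  expect_equal(haar_inverse(c(4, rep(0, 31))), rep(4, 32))
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(32)
    expect_equal(haar_inverse(haar_full(x)), x, tolerance = 1e-10)
    expect_equal(haar_inverse(haar_full(x, "orthonormal"), "orthonormal"),
                 x, tolerance = 1e-10)
  }
  # orthonormal convention preserves energy (Parseval)
  x <- rnorm(32)
  expect_equal(sum(haar_full(x, "orthonormal")^2), sum(x^2),
               tolerance = 1e-10)
})

test_that("PCA basis is complete, orthonormal and deterministic in sign", {
  set.seed(21)
  x <- matrix(rnorm(200 * 32), 200)
  b <- fit_pca(x)
  expect_identical(ncol(b$rotation), 32L)
  expect_equal(crossprod(b$rotation), diag(32), tolerance = 1e-8)
  expect_true(all(diff(b$var_explained) <= 1e-12))
  expect_true(all(vapply(1:32, function(k) {
    b$rotation[which.max(abs(b$rotation[, k])), k] > 0
  }, logical(1))))
  expect_error(fit_pca(x[1:10, ]), "insufficient-samples")
})

test_that("rank-1 data yields its generating direction as PC1", {
  u <- rep(1 / sqrt(32), 32)
  t_coef <- seq(-5, 5, length.out = 100)
  x <- outer(rep(1, 100), rnorm(32)) + outer(t_coef, u)
  b <- fit_pca(x)
  expect_equal(abs(sum(b$rotation[, 1] * u)), 1, tolerance = 1e-8)
  expect_equal(b$var_explained[1], 1, tolerance = 1e-8)
})

test_that("explained variance tracks the generating covariance", {
  set.seed(33)
  eig <- seq(32, 1)            # diagonal covariance with known spectrum
  x <- matrix(rnorm(10000 * 32), 10000) %*% diag(sqrt(eig))
  b <- fit_pca(x)
  expect_equal(b$var_explained, eig / sum(eig), tolerance = 0.02)
})

test_that("projection is exact on basis directions and complete at k = 32", {
  set.seed(34)
  x <- matrix(rnorm(100 * 32), 100)
  b <- fit_pca(x)
  expect_equal(as.numeric(project_pca(b$mean, b, 4)), rep(0, 4),
               tolerance = 1e-10)
  probe <- b$mean + 2 * b$rotation[, 1]
  expect_equal(as.numeric(project_pca(probe, b, 4)), c(2, 0, 0, 0),
               tolerance = 1e-8)
  # completeness: reconstruction from all 32 projections
  proj <- project_pca(x, b, 32)
  recon <- sweep(proj %*% t(b$rotation), 2, -b$mean)
  expect_equal(recon, x, tolerance = 1e-10, ignore_attr = TRUE)
  # Parseval on the centered rows
  centered <- sweep(x, 2, b$mean)
  expect_equal(rowSums(proj^2), rowSums(centered^2), tolerance = 1e-8)
})

test_that("extract_features produces labeled per-voxel feature tables", {
  ph <- phantom_fix(noise = 0.02)
  aif <- extract_aif(ph$series, ph$artery_mask, baseline_frames = 10)
  win <- preprocess_series(ph$series, ph$tumor_mask, aif)
  wt <- extract_features(win, "wt")
  expect_identical(dim(wt$features), c(nrow(win), 32L))
  expect_identical(colnames(wt$features)[1], "A5")
  pca <- extract_features(win, "pca", k = 4)
  expect_identical(dim(pca$features), c(nrow(win), 4L))
  expect_s3_class(attr(pca, "basis"), "dce_pca")
  sel <- select_features(wt, c(1L, 5L, 9L, 18L))
  expect_identical(colnames(sel$features), c("A5", "D3.1", "D2.1", "D1.2"))
})
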