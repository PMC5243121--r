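test_that("baseline is the mean of the pre-onset frames", {
  expect_equal(estimate_baseline(rep(100, 20), 5), 100)
  expect_equal(estimate_baseline(c(90, 100, 110, 500, 600), 3), 100)
  expect_error(estimate_baseline(1:10, 2), "3 pre-onset")
})

test_that("normalization divides enhancement by S0 and the AIF peak", {
  expect_equal(normalize_curve(150, s0 = 100, aif_max = 2.5), 0.2)
  expect_equal(normalize_curve(rep(100, 10), 100, 2.5), rep(0, 10))
  expect_error(normalize_curve(150, 100, 0), "positive")
  expect_error(normalize_curve(150, 0, 2.5), "nonpositive-baseline")
})

test_that("normalization is invariant to a global signal rescaling", {
  set.seed(42)
  for (c_scale in c(0.5, 3, 100)) {
    s <- 100 + cumsum(runif(40))
    a <- normalize_curve(s, 100, 2.5)
    b <- normalize_curve(c_scale * s, c_scale * 100, 2.5)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("AIF extraction recovers the phantom onset and allows overrides", {
  ph <- phantom_fix(noise = 0, small = TRUE)
  aif <- extract_aif(ph$series, ph$artery_mask, baseline_frames = 10)
  # noise-free: detected onset is the first enhancing sample of the truth
  expect_identical(aif$onset_index, min(which(ph$aif_curve > 0)))
  expect_equal(max(aif$curve), aif$peak_enhancement)
  # the AIF's own normalized peak is 1 by construction
  expect_equal(max(aif$curve) / aif$peak_enhancement, 1)
  # manual override is echoed back
  man <- extract_aif(ph$series, ph$artery_mask, baseline_frames = 10,
                     onset_index = 7L, peak_enhancement = 3.3)
  expect_identical(man$onset_index, 7L)
  expect_identical(man$peak_enhancement, 3.3)
})

test_that("AIF extraction fails cleanly on empty or flat regions", {
  ph <- phantom_fix(noise = 0, small = TRUE)
  empty <- array(FALSE, dim(ph$tumor_mask))
  expect_error(extract_aif(ph$series, empty), "aif-not-found")
  flat <- array(100, dim(ph$series))
  expect_error(extract_aif(flat, ph$artery_mask), "aif-not-found")
})

test_that("windowing selects 32 frames from the onset inclusive", {
  s <- seq_len(60)
  w <- window_curve(s, onset_index = 11)   # onset at the 11th frame
  expect_length(w, 32)
  expect_identical(w, 11:42)
  expect_error(window_curve(s, onset_index = 41), "window-overrun")
  # onset alignment: shifting the series and the onset together is a no-op
  set.seed(7)
  x <- rnorm(60)
  for (k in c(1, 3, 8)) {
    shifted <- c(rep(0, k), x)[1:60]
    expect_identical(window_curve(shifted, 5 + k), window_curve(x, 5))
  }
})

test_that("resampling is exact on linear data and counts samples correctly", {
  ramp <- 2 * (0:31) * 7.7 + 5
  out <- resample_curve(ramp, dt_in = 7.7, dt_out = 4.1)
  expect_length(out, floor(31 * 7.7 / 4.1) + 1)   # 59 samples
  t_out <- (seq_along(out) - 1) * 4.1
  expect_equal(out, 2 * t_out + 5, tolerance = 1e-9)
  # identity resample returns the input grid values
  expect_equal(resample_curve(ramp, 7.7, 7.7), ramp, tolerance = 1e-9)
  expect_error(resample_curve(ramp, 7.7, 1000), "span")
})

test_that("preprocessing excludes voxels with nonpositive baseline", {
  ph <- phantom_fix(noise = 0, small = TRUE)
  aif <- extract_aif(ph$series, ph$artery_mask, baseline_frames = 10)
  series <- ph$series
  bad <- which(ph$tumor_mask)[1]
  flat_idx <- arrayInd(bad, dim(ph$tumor_mask))
  series[flat_idx[1], flat_idx[2], flat_idx[3], ] <- 0
  win <- preprocess_series(series, ph$tumor_mask, aif)
  exc <- attr(win, "excluded")
  expect_identical(exc$voxel, bad)
  expect_identical(exc$reason, "nonpositive-baseline")
  expect_identical(nrow(win) + 1L, sum(ph$tumor_mask))
  expect_identical(ncol(win$window), 32L)
})
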