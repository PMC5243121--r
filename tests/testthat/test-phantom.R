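test_that("AIF model validates its parameters", {
  expect_error(aif_model(peak_enhancement = 0), "positive")
  expect_error(aif_model(peak_enhancement = -1), "positive")
  expect_error(generate_aif(aif_model(onset_time_s = 500),
                            acquisition_config()),
               "aif-onset-out-of-range")
})

test_that("AIF curve is zero before onset and peaks at peak_enhancement", {
  cfg <- acquisition_config()
  curve <- generate_aif(aif_model(onset_time_s = 30, peak_enhancement = 2.5),
                        cfg)
  expect_equal(curve[1:10], rep(0, 10))   # samples at t = 0..27 s
  expect_equal(max(curve), 2.5, tolerance = 1e-9)
})

test_that("gamma-variate peak lands at the analytic mode alpha*beta", {
  # brute-force oracle: evaluate the same model on a dense grid and find
  # the continuous-time maximum, then compare with the sampled argmax
  model <- aif_model(onset_time_s = 30, alpha = 3, beta_s = 4)
  cfg <- acquisition_config(dt_seconds = 3)
  tau_dense <- seq(0, 60, by = 0.001)
  shape <- (tau_dense / 12)^3 * exp(3 - tau_dense / 4)  # alpha*beta = 12 s
  t_mode_dense <- tau_dense[which.max(shape)] + 30
  expect_equal(t_mode_dense, 30 + 3 * 4, tolerance = 1e-3)
  curve <- generate_aif(model, cfg)
  t_argmax <- (which.max(curve) - 1) * cfg$dt_seconds
  expect_equal(t_argmax, round(t_mode_dense / 3) * 3)
})

test_that("Tofts forward model handles degenerate parameter sets", {
  cfg <- acquisition_config()
  aif <- generate_aif(aif_model(), cfg)
  zero <- tofts_forward(aif, list(vp = 0, ktrans = 0, kep = 0), cfg)
  expect_equal(zero, rep(0, cfg$n_frames))
  plasma <- tofts_forward(aif, list(vp = 0.1, ktrans = 0, kep = 0.5), cfg)
  expect_identical(plasma, 0.1 * aif)
  expect_error(tofts_forward(aif, list(vp = 0.1, ktrans = -1, kep = 0.5), cfg),
               "non-negative")
  expect_error(tissue_params(1.2, 0.1, 0.1), "vp")
})

test_that("trapezoid convolution matches a dense-grid oracle on a boxcar AIF", {
  cfg <- acquisition_config(n_frames = 60L, dt_seconds = 3)
  times <- acquisition_times(cfg)
  boxcar <- as.numeric(times >= 30 & times < 60)
  p <- list(vp = 0.05, ktrans = 0.2, kep = 0.5)
  got <- tofts_forward(boxcar, p, cfg)
  # oracle: same trapezoid convolution on a 100x finer grid of the same
  # piecewise-linear interpolant of the sampled AIF
  t_fine <- seq(0, max(times), by = cfg$dt_seconds / 100)
  cp_fine <- approx(times, boxcar, xout = t_fine)$y
  conv_fine <- vapply(times, function(tt) {
    keep <- t_fine <= tt
    if (sum(keep) < 2) return(0)
    integrand <- cp_fine[keep] * exp(-(p$kep / 60) * (tt - t_fine[keep]))
    sum(diff(t_fine[keep]) * (head(integrand, -1) + tail(integrand, -1)) / 2)
  }, numeric(1))
  oracle <- p$vp * boxcar + (p$ktrans / 60) * conv_fine
  expect_lt(max(abs(got - oracle)) / max(abs(oracle)), 0.01)
})

test_that("tissue enhancement is pointwise non-decreasing in vp", {
  cfg <- acquisition_config()
  aif <- generate_aif(aif_model(), cfg)
  vps <- seq(0, 0.3, by = 0.05)
  curves <- t(vapply(vps, function(v) {
    tofts_forward(aif, list(vp = v, ktrans = 0.2, kep = 0.6), cfg)
  }, numeric(cfg$n_frames)))
  expect_true(all(diff(curves) >= 0))
})

test_that("phantom generation is deterministic and labels match construction", {
  ph1 <- generate_phantom(acquisition_config(noise_sd_rel = 0.02, seed = 17))
  ph2 <- generate_phantom(acquisition_config(noise_sd_rel = 0.02, seed = 17))
  expect_identical(ph1$series, ph2$series)
  expect_identical(ph1$truth$label, ph2$truth$label)

  labels <- ph1$truth$label[ph1$tumor_mask]
  # labels are defined by the blob construction; the labeled fraction must
  # equal the constructed blob fraction
  expect_equal(mean(labels == 0), ph1$truth$lbv_fraction, tolerance = 0.02)
  # and truth labels agree with thresholding the truth BV map
  expect_identical(labels,
                   label_by_bv(ph1$truth$bv_percent[ph1$tumor_mask]))
})

test_that("noise-free phantom voxels with vp = 0 stay flat at S0", {
  cfg <- acquisition_config(noise_sd_rel = 0)
  ph <- generate_phantom(cfg)
  # background voxels have no tracer: constant S0
  bg <- which(!ph$tumor_mask & !ph$artery_mask)[1]
  flat <- matrix(ph$series, prod(dim(ph$series)[1:3]), cfg$n_frames)
  expect_equal(flat[bg, ], rep(ph$s0, cfg$n_frames))
})

test_that("overlapping artery and tumor masks are rejected", {
  geo <- phantom_geometry(artery_corner = c(18L, 18L, 7L))
  expect_error(generate_phantom(geometry = geo), "overlap")
})

test_that("disjoint vp class ranges are enforced", {
  expect_error(generate_phantom(lbv_vp = c(0.01, 0.09)), "opposite sides")
})
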