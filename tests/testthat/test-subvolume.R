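test_that("probability scatter respects the mask and round-trips", {
  mask <- array(FALSE, c(4, 4, 2)); mask[2:3, 2:3, ] <- TRUE
  idx <- which(mask)
  p <- seq_along(idx) / length(idx)
  map <- assemble_maps(p, idx, mask)
  expect_equal(map[idx], p)                      # gather returns the input
  expect_true(all(is.nan(map[!mask])))
  expect_identical(attr(map, "n_unassigned"), 0L)
  ones <- assemble_maps(rep(1, length(idx)), idx, mask)
  expect_true(all(ones[mask] == 1))
  expect_error(assemble_maps(0.5, which(!mask)[1], mask), "outside")
})

test_that("the minimum-volume filter implements the 1-cc exclusion", {
  vox <- c(1.56, 1.56, 1.5)                      # 3.65 mm^3 per voxel
  mk <- function(n_vox) {
    m <- array(FALSE, c(20, 20, 10))
    m[seq_len(min(n_vox, 8000))] <- FALSE
    # cube-ish component: fill consecutive voxels of a 10x10xk block
    filled <- 0
    for (z in 1:10) for (y in 1:10) for (x in 1:10) {
      if (filled < n_vox) { m[x, y, z] <- TRUE; filled <- filled + 1 }
    }
    m
  }
  big <- extract_subvolume(mk(300), voxel_dims_mm = vox)     # 1095 mm^3
  expect_identical(sum(big$mask), 300L)
  expect_true(all(big$components$kept))
  small <- extract_subvolume(mk(200), voxel_dims_mm = vox)   # 730 mm^3
  expect_identical(sum(small$mask), 0L)
  expect_false(any(small$components$kept))
})

test_that("diagonal neighbors merge at 26- but not 6-connectivity", {
  m <- array(FALSE, c(4, 4, 4))
  m[2, 2, 2] <- TRUE; m[3, 3, 3] <- TRUE
  c26 <- extract_subvolume(m, min_volume_cc = 0, connectivity = 26L,
                           voxel_dims_mm = c(1, 1, 1))
  expect_identical(nrow(c26$components), 1L)
  c6 <- extract_subvolume(m, min_volume_cc = 0, connectivity = 6L,
                          voxel_dims_mm = c(1, 1, 1))
  expect_identical(nrow(c6$components), 2L)
})

test_that("NaN probabilities are treated as below threshold", {
  p <- array(NaN, c(3, 3, 3)); p[1, 1, 1] <- 0.9
  s <- extract_subvolume(p, min_volume_cc = 0, voxel_dims_mm = c(1, 1, 1))
  expect_identical(sum(s$mask), 1L)
  # exactly at the threshold is not low BV (strict >)
  p[2, 2, 2] <- 0.5
  s2 <- extract_subvolume(p, min_volume_cc = 0, voxel_dims_mm = c(1, 1, 1))
  expect_identical(sum(s2$mask), 1L)
})

test_that("voxel accuracy counts agreements in percent", {
  expect_equal(voxel_accuracy(c(0, 1, 1), c(0, 1, 1)), 100)
  expect_equal(voxel_accuracy(c(0, 1), c(1, 0)), 0)
  pred <- c(rep(0, 82), rep(1, 18)); ref <- c(rep(0, 82), rep(0, 18))
  expect_equal(voxel_accuracy(pred, ref), 82)
  expect_error(voxel_accuracy(1:3, 1:4), "equal length")
})

test_that("Dice coefficient matches its definition and is symmetric", {
  g <- array(FALSE, c(10, 10, 2)); r <- g
  g[1:100] <- TRUE
  r[41:140] <- TRUE                     # |G| = |R| = 100, overlap 60
  expect_equal(dice(g, r), 0.6)
  expect_equal(dice(g, r), dice(r, g))
  expect_equal(dice(g, g), 1)
  disj <- array(FALSE, dim(g)); disj[150:160] <- TRUE
  expect_equal(dice(g, disj), 0)
  empty <- array(FALSE, dim(g))
  expect_warning(out <- dice(empty, empty), "empty")
  expect_true(is.nan(out))
  expect_error(dice(g, array(FALSE, c(5, 5, 2))), "different grids")
})

test_that("adding a shared voxel never decreases the Dice coefficient", {
  set.seed(13)
  g <- array(runif(200) > 0.6, c(10, 10, 2))
  r <- array(runif(200) > 0.6, c(10, 10, 2))
  d0 <- dice(g, r)
  free <- which(!g & !r)
  for (v in free[1:10]) {
    g2 <- g; r2 <- r; g2[v] <- TRUE; r2[v] <- TRUE
    expect_gte(dice(g2, r2), d0)
  }
})
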