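# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

ellipsoid_mask <- function(dim, center, semiaxes) {
  x <- (seq_len(dim[1]) - center[1]) / semiaxes[1]
  y <- (seq_len(dim[2]) - center[2]) / semiaxes[2]
  z <- (seq_len(dim[3]) - center[3]) / semiaxes[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

#' Phantom geometry specification
#'
#' Describes the voxel grid, the ellipsoidal tumor, the low-blood-volume
#' blobs embedded in it, and the artery region used to carry the AIF. The
#' default geometry places a ~3000-voxel tumor on a 40 x 40 x 16 grid with
#' two low-BV blobs occupying roughly a quarter of the tumor.
#'
#' @param dim Integer length-3 grid size.
#' @param tumor_center,tumor_semiaxes Ellipsoid center and semi-axes
#'   (voxels).
#' @param lbv_blobs List of ellipsoidal blobs, each a list with `center`
#'   and `semiaxes`; voxels inside any blob (and inside the tumor) are the
#'   true low-BV class.
#' @param artery_corner,artery_size Origin (1-based voxel) and extent of
#'   the rectangular artery region.
#' @return An object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(dim = c(40L, 40L, 16L),
                             tumor_center = c(20, 20, 8),
                             tumor_semiaxes = c(11, 11, 6),
                             lbv_blobs = list(
                               list(center = c(15, 16, 7), semiaxes = c(5, 5, 3.2)),
                               list(center = c(25, 24, 9), semiaxes = c(4.5, 5, 3.4))),
                             artery_corner = c(2L, 2L, 2L),
                             artery_size = c(3L, 3L, 4L)) {
  stopifnot(length(dim) == 3L, all(dim >= 1))
  structure(list(dim = as.integer(dim), tumor_center = tumor_center,
                 tumor_semiaxes = tumor_semiaxes, lbv_blobs = lbv_blobs,
                 artery_corner = as.integer(artery_corner),
                 artery_size = as.integer(artery_size)),
            class = "phantom_geometry")
}

#' @rdname phantom_geometry
#' @details `phantom_geometry_small()` is a reduced grid (24 x 24 x 10,
#'   ~450 tumor voxels) intended for quick demonstrations and for
#'   fit-intensive checks such as voxelwise pharmacokinetic recovery.
#' @export
phantom_geometry_small <- function() {
  phantom_geometry(dim = c(24L, 24L, 10L),
                   tumor_center = c(13, 13, 5.5),
                   tumor_semiaxes = c(6, 6, 3.5),
                   lbv_blobs = list(
                     list(center = c(10.5, 11, 5), semiaxes = c(3, 3, 2.2)),
                     list(center = c(16, 15.5, 6), semiaxes = c(2.4, 2.6, 2))),
                   artery_corner = c(2L, 2L, 2L),
                   artery_size = c(2L, 2L, 3L))
}

#' Generate a seeded digital DCE-MRI phantom
#'
#' Builds a synthetic 4D signal-intensity series with known voxelwise
#' kinetics. Tumor voxels follow the two-compartment Tofts forward model
#' driven by an analytic AIF; voxels inside the low-BV blobs draw
#' `vp ~ U(lbv_vp)` and the remaining tumor voxels draw `vp ~ U(hbv_vp)`,
#' so the true class of every voxel is known by construction (the two
#' ranges must sit on opposite sides of the BV threshold). `ktrans` is
#' drawn uniformly and `kep = ktrans / ve` with `ve ~ U(ve_range)`, adding
#' realistic curve-shape diversity that is independent of the class.
#' Artery voxels carry the AIF enhancement itself. Enhancement is converted
#' to signal as `S(t) = S0 * (1 + dS(t))` and independent Gaussian noise
#' with standard deviation `noise_sd_rel * S0` is added to every voxel.
#'
#' The generator is fully reproducible: the same configuration and seed
#' give a bit-identical phantom.
#'
#' @param cfg An [acquisition_config()]; its `seed` and `noise_sd_rel`
#'   control the randomness.
#' @param geometry A [phantom_geometry()].
#' @param aif An [aif_model()].
#' @param lbv_vp,hbv_vp Ranges (length 2) for the plasma fraction of the
#'   low- and high-BV classes.
#' @param ktrans_range Range for `ktrans` (1/min).
#' @param ve_range Range for the extravascular extracellular fraction used
#'   to derive `kep = ktrans / ve`.
#' @param s0 Baseline signal intensity.
#' @param bv_threshold BV labeling threshold in percent.
#' @return An object of class `dce_phantom`: a list with the 4D `series`,
#'   logical `tumor_mask` and `artery_mask`, the ground `truth` (maps of
#'   `vp`, `ktrans`, `kep`, `bv_percent` and the 0/1 `label`, `NA` outside
#'   the tumor), the noise-free `aif_curve`, and the generating objects.
#' @examples
#' ph <- generate_phantom(acquisition_config(noise_sd_rel = 0))
#' sum(ph$tumor_mask)
#' @export
generate_phantom <- function(cfg = acquisition_config(),
                             geometry = phantom_geometry(),
                             aif = aif_model(),
                             lbv_vp = c(0.01, 0.05),
                             hbv_vp = c(0.10, 0.25),
                             ktrans_range = c(0.05, 0.5),
                             ve_range = c(0.2, 0.5),
                             s0 = 100,
                             bv_threshold = 7.6) {
  stopifnot(inherits(cfg, "acquisition_config"),
            inherits(geometry, "phantom_geometry"))
  if (max(lbv_vp) * 100 >= bv_threshold || min(hbv_vp) * 100 < bv_threshold) {
    stop("generate_phantom: lbv_vp and hbv_vp ranges must lie on opposite ",
         "sides of the BV threshold so truth labels are unambiguous",
         call. = FALSE)
  }
  dm <- geometry$dim
  tumor_mask <- ellipsoid_mask(dm, geometry$tumor_center, geometry$tumor_semiaxes)
  blob_mask <- array(FALSE, dm)
  for (b in geometry$lbv_blobs) {
    blob_mask <- blob_mask | ellipsoid_mask(dm, b$center, b$semiaxes)
  }
  blob_mask <- blob_mask & tumor_mask
  artery_mask <- array(FALSE, dm)
  ac <- geometry$artery_corner; as_ <- geometry$artery_size
  artery_mask[ac[1]:(ac[1] + as_[1] - 1L),
              ac[2]:(ac[2] + as_[2] - 1L),
              ac[3]:(ac[3] + as_[3] - 1L)] <- TRUE
  if (any(artery_mask & tumor_mask)) {
    stop("generate_phantom: artery and tumor masks overlap", call. = FALSE)
  }

  times <- acquisition_times(cfg)
  aif_curve <- generate_aif(aif, cfg)
  tum_idx <- which(tumor_mask)
  n_tum <- length(tum_idx)
  is_lbv <- blob_mask[tum_idx]

  with_seed(cfg$seed, {
    vp <- numeric(n_tum)
    vp[is_lbv] <- stats::runif(sum(is_lbv), lbv_vp[1], lbv_vp[2])
    vp[!is_lbv] <- stats::runif(sum(!is_lbv), hbv_vp[1], hbv_vp[2])
    ktrans <- stats::runif(n_tum, ktrans_range[1], ktrans_range[2])
    ve <- stats::runif(n_tum, ve_range[1], ve_range[2])
    kep <- ktrans / ve

    enh <- tofts_forward_matrix(aif_curve, vp, ktrans, kep, times)

    n_t <- cfg$n_frames
    series <- array(s0, c(dm, n_t))
    flat <- matrix(series, prod(dm), n_t)
    flat[tum_idx, ] <- s0 * (1 + enh)
    flat[which(artery_mask), ] <-
      matrix(s0 * (1 + aif_curve), sum(artery_mask), n_t, byrow = TRUE)
    if (cfg$noise_sd_rel > 0) {
      flat <- flat + stats::rnorm(length(flat), sd = cfg$noise_sd_rel * s0)
    }
    series <- array(flat, c(dm, n_t))
  }) -> series

  param_map <- function(v) {
    m <- array(NA_real_, dm); m[tum_idx] <- v; m
  }
  bv_map <- param_map(100 * vp)
  label_map <- array(NA_integer_, dm)
  label_map[tum_idx] <- label_by_bv(100 * vp, bv_threshold)

  structure(
    list(series = series,
         tumor_mask = tumor_mask,
         artery_mask = artery_mask,
         truth = list(vp = param_map(vp), ktrans = param_map(ktrans),
                      kep = param_map(kep), bv_percent = bv_map,
                      label = label_map,
                      lbv_fraction = mean(is_lbv)),
         aif_curve = aif_curve,
         aif_model = aif,
         cfg = cfg,
         geometry = geometry,
         s0 = s0,
         bv_threshold = bv_threshold),
    class = "dce_phantom"
  )
}

#' @export
print.dce_phantom <- function(x, ...) {
  dm <- dim(x$series)
  cat("<dce_phantom> ", paste(dm[1:3], collapse = " x "), " grid, ",
      dm[4], " frames at ", x$cfg$dt_seconds, " s\n", sep = "")
  cat("  tumor voxels: ", sum(x$tumor_mask),
      " (low-BV fraction ", round(x$truth$lbv_fraction, 3), ")\n", sep = "")
  cat("  artery voxels: ", sum(x$artery_mask),
      ", noise SD (rel. to S0): ", x$cfg$noise_sd_rel, "\n", sep = "")
  invisible(x)
}

#' Tumor voxel records of a phantom
#'
#' Flattens the phantom's tumor voxels into a tibble, one row per voxel,
#' with grid coordinates, ground-truth kinetics and label, and the raw
#' signal curve as a matrix column `signal` (`n_vox x n_frames`).
#'
#' @param phantom A [generate_phantom()] result.
#' @return A tibble with columns `voxel`, `x`, `y`, `z`, `vp`, `bv_percent`,
#'   `label`, and matrix column `signal`.
#' @export
phantom_curves <- function(phantom) {
  stopifnot(inherits(phantom, "dce_phantom"))
  dm <- dim(phantom$series)[1:3]
  idx <- which(phantom$tumor_mask)
  coord <- arrayInd(idx, dm)
  flat <- matrix(phantom$series, prod(dm), dim(phantom$series)[4])
  tibble::tibble(
    voxel = idx,
    x = coord[, 1], y = coord[, 2], z = coord[, 3],
    vp = phantom$truth$vp[idx],
    bv_percent = phantom$truth$bv_percent[idx],
    label = phantom$truth$label[idx],
    signal = flat[idx, , drop = FALSE]
  )
}
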