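#' Voxelwise tissue kinetic parameters
#'
#' Parameters of the two-compartment Tofts model: plasma volume fraction
#' `vp` (dimensionless, in `[0, 1]`), transfer constant `ktrans` (per
#' minute) and efflux rate `kep` (per minute).
#'
#' @param vp Plasma volume fraction in `[0, 1]`.
#' @param ktrans Volume transfer constant, 1/min, >= 0.
#' @param kep Efflux rate constant, 1/min, >= 0.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(vp, ktrans, kep) {
  stopifnot(is.finite(vp), is.finite(ktrans), is.finite(kep))
  if (vp < 0 || vp > 1) stop("tissue_params: vp must be in [0, 1]", call. = FALSE)
  if (ktrans < 0 || kep < 0) {
    stop("tissue_params: rate constants must be non-negative", call. = FALSE)
  }
  structure(list(vp = as.numeric(vp), ktrans = as.numeric(ktrans),
                 kep = as.numeric(kep)),
            class = "tissue_params")
}

# Exponentially weighted running trapezoid integral of cp against
# exp(-kep_s * (t_i - tau)) on the sample grid. kep_s is per second.
# Uses the exact recursion
#   I_i = I_{i-1} * e^{-kep_s dt_i} + dt_i/2 * (cp_{i-1} e^{-kep_s dt_i} + cp_i)
# which reproduces the full trapezoid sum at every time point.
tofts_convolve <- function(cp, times, kep_s) {
  n <- length(cp)
  out <- numeric(n)
  if (n < 2) return(out)
  acc <- 0
  for (i in 2:n) {
    dt <- times[i] - times[i - 1]
    decay <- exp(-kep_s * dt)
    acc <- acc * decay + dt / 2 * (cp[i - 1] * decay + cp[i])
    out[i] <- acc
  }
  out
}

#' Forward two-compartment Tofts model
#'
#' Computes the tissue enhancement curve
#' `C_t(t) = vp * Cp(t) + Ktrans * integral_0^t Cp(tau) exp(-kep (t - tau)) dtau`
#' from a plasma (AIF) curve, using the trapezoid rule for the convolution
#' on the acquisition sample grid. The signal is assumed linear in
#' concentration, so both input and output are in relative-enhancement
#' units. Rate constants are per minute; the time axis is in seconds.
#'
#' @param aif_curve Plasma enhancement curve (numeric vector).
#' @param params A [tissue_params()] object, or a list with `vp`, `ktrans`,
#'   `kep`.
#' @param cfg An [acquisition_config()], or `NULL` if `times` is given.
#' @param times Optional explicit sample times in seconds (overrides `cfg`).
#' @return Tissue enhancement curve, same length as `aif_curve`.
#' @examples
#' cfg <- acquisition_config()
#' aif <- generate_aif(aif_model(), cfg)
#' tofts_forward(aif, tissue_params(0.05, 0.2, 0.5), cfg)
#' @export
tofts_forward <- function(aif_curve, params, cfg = NULL, times = NULL) {
  if (is.null(times)) {
    stopifnot(inherits(cfg, "acquisition_config"))
    times <- acquisition_times(cfg)
  }
  stopifnot(length(aif_curve) == length(times))
  if (params$ktrans < 0 || params$kep < 0) {
    stop("tofts_forward: rate constants must be non-negative", call. = FALSE)
  }
  kep_s <- params$kep / 60
  ktrans_s <- params$ktrans / 60
  params$vp * aif_curve + ktrans_s * tofts_convolve(aif_curve, times, kep_s)
}

# Vectorized forward model over many voxels: vp, ktrans, kep are vectors of
# length n_vox; returns an n_vox x n_time matrix. Same recursion as
# tofts_convolve, advanced one time step at a time for all voxels at once.
tofts_forward_matrix <- function(aif_curve, vp, ktrans, kep, times) {
  n_vox <- length(vp)
  n_t <- length(times)
  stopifnot(length(ktrans) == n_vox, length(kep) == n_vox,
            length(aif_curve) == n_t)
  kep_s <- kep / 60
  conv <- matrix(0, n_vox, n_t)
  acc <- numeric(n_vox)
  for (i in seq_len(n_t)[-1]) {
    dt <- times[i] - times[i - 1]
    decay <- exp(-kep_s * dt)
    acc <- acc * decay + dt / 2 * (aif_curve[i - 1] * decay + aif_curve[i])
    conv[, i] <- acc
  }
  outer(vp, aif_curve) + (ktrans / 60) * conv
}

#' Fit the two-compartment Tofts model to a normalized curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with box
#' constraints) of the forward model to a normalized tissue enhancement
#' curve, with three fixed multi-start initializations; the start with the
#' lowest residual sum of squares wins. Bounds: `vp` in `[0, 1]`, `ktrans`
#' in `[0, 5]` 1/min, `kep` in `[0, 10]` 1/min.
#'
#' A voxel where every start fails is returned with `NaN` parameters and
#' `converged = FALSE` rather than raising an error, so that map-level
#' fitting can skip it.
#'
#' @param curve Normalized tissue enhancement curve (length >= 16).
#' @param aif_curve Normalized AIF curve, same length.
#' @param times Sample times in seconds, same length.
#' @return A list with `vp`, `ktrans`, `kep`, `rss` (residual sum of
#'   squares) and `converged`.
#' @export
fit_tofts <- function(curve, aif_curve, times) {
  n <- length(curve)
  stopifnot(length(aif_curve) == n, length(times) == n)
  if (n < 16) stop("fit_tofts: need at least 16 time points", call. = FALSE)

  lower <- c(vp = 0, ktrans = 0, kep = 0)
  upper <- c(vp = 1, ktrans = 5, kep = 10)
  starts <- list(c(vp = 0.02, ktrans = 0.1, kep = 0.3),
                 c(vp = 0.10, ktrans = 0.3, kep = 0.8),
                 c(vp = 0.30, ktrans = 1.0, kep = 2.0))
  resid_fn <- function(p) {
    tofts_forward(aif_curve,
                  list(vp = p[[1]], ktrans = p[[2]], kep = p[[3]]),
                  times = times) - curve
  }

  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-8, ptol = 1e-8, maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = fit$par, rss = rss,
                   converged = fit$info %in% 1:4)
    }
  }
  if (is.null(best)) {
    return(list(vp = NaN, ktrans = NaN, kep = NaN, rss = NaN,
                converged = FALSE))
  }
  list(vp = unname(best$par[[1]]), ktrans = unname(best$par[[2]]),
       kep = unname(best$par[[3]]), rss = best$rss,
       converged = best$converged)
}

#' Label voxels as low or high blood volume
#'
#' Applies the blood-volume threshold separating low-BV (label 0) from
#' high-BV (label 1) voxels: label 0 iff `bv_percent < threshold`. A voxel
#' exactly at the threshold is assigned high BV. The 7.6% default is the
#' clinically established cutoff for poorly perfused head-and-neck tumor
#' tissue.
#'
#' @param bv_percent Numeric vector or array of blood-volume percentages.
#' @param threshold Threshold in percent (default 7.6).
#' @return Integer labels (0 = low BV, 1 = high BV), same shape as input;
#'   `NA` input propagates to `NA`.
#' @examples
#' label_by_bv(c(0, 7.59, 7.6, 20))   # 0 0 1 1
#' @export
label_by_bv <- function(bv_percent, threshold = 7.6) {
  out <- ifelse(bv_percent < threshold, 0L, 1L)
  if (is.array(bv_percent)) array(out, dim(bv_percent)) else out
}

#' Fit blood-volume and label maps for all tumor voxels
#'
#' Runs [fit_tofts()] on each in-mask normalized curve and derives the
#' blood-volume map as `bv_scale * vp` (default `BV% = 100 * vp`, i.e. no
#' hematocrit correction) and the corresponding low/high-BV label map.
#'
#' @param curves `n_vox x n_time` matrix of normalized tissue curves.
#' @param aif_curve Normalized AIF curve.
#' @param times Sample times (seconds).
#' @param bv_scale Factor converting `vp` to BV percent (default 100).
#' @param bv_threshold Labeling threshold in percent (default 7.6).
#' @return A tibble with one row per voxel: `vp`, `ktrans`, `kep`,
#'   `bv_percent`, `label`, `rss`, `converged`.
#' @export
fit_bv <- function(curves, aif_curve, times, bv_scale = 100,
                   bv_threshold = 7.6) {
  stopifnot(is.matrix(curves), ncol(curves) == length(aif_curve))
  fits <- lapply(seq_len(nrow(curves)), function(i) {
    fit_tofts(curves[i, ], aif_curve, times)
  })
  vp <- vapply(fits, `[[`, numeric(1), "vp")
  tibble::tibble(
    voxel = seq_len(nrow(curves)),
    vp = vp,
    ktrans = vapply(fits, `[[`, numeric(1), "ktrans"),
    kep = vapply(fits, `[[`, numeric(1), "kep"),
    bv_percent = bv_scale * vp,
    label = label_by_bv(bv_scale * vp, bv_threshold),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    converged = vapply(fits, `[[`, logical(1), "converged")
  )
}
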