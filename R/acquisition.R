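#' Acquisition configuration for a dynamic contrast-enhanced series
#'
#' Bundles the temporal and spatial sampling parameters of a DCE-MRI
#' acquisition together with the phantom noise level and seed. Two presets
#' cover the acquisition dialects the pipeline is designed around: a
#' TWIST-like protocol (60 frames at ~3 s, 1.56 x 1.56 x 1.5 mm voxels) and
#' a coarser gradient-echo protocol (32 frames at ~7.7 s, 2 mm isotropic).
#'
#' @param n_frames Number of dynamic frames (time points).
#' @param dt_seconds Temporal resolution in seconds (> 0).
#' @param voxel_dims_mm Length-3 numeric, voxel edge lengths in mm.
#' @param baseline_frames Number of pre-contrast frames preceding the AIF
#'   onset; at least 3 are needed for baseline estimation.
#' @param noise_sd_rel Standard deviation of additive Gaussian noise on the
#'   signal, expressed relative to the baseline signal `S0` (0 = noise-free).
#' @param seed Integer seed controlling all randomness in phantom generation.
#'
#' @return An object of class `acquisition_config` (a named list).
#' @examples
#' acquisition_config()                 # native 3 s / 60 frame dialect
#' acquisition_config_coarse()          # 7.7 s / 32 frame dialect
#' @export
acquisition_config <- function(n_frames = 60L,
                               dt_seconds = 3,
                               voxel_dims_mm = c(1.56, 1.56, 1.5),
                               baseline_frames = 10L,
                               noise_sd_rel = 0.02,
                               seed = 17L) {
  n_frames <- as.integer(n_frames)
  baseline_frames <- as.integer(baseline_frames)
  stopifnot(length(n_frames) == 1L, n_frames >= 1L,
            length(dt_seconds) == 1L, is.finite(dt_seconds), dt_seconds > 0,
            length(voxel_dims_mm) == 3L, all(voxel_dims_mm > 0),
            baseline_frames >= 0L)
  if (n_frames < baseline_frames + 32L) {
    stop("acquisition_config: n_frames must be >= baseline_frames + 32 ",
         "so a 32-point dyadic window fits after the enhancement onset",
         call. = FALSE)
  }
  structure(
    list(n_frames = n_frames,
         dt_seconds = as.numeric(dt_seconds),
         voxel_dims_mm = as.numeric(voxel_dims_mm),
         baseline_frames = baseline_frames,
         noise_sd_rel = as.numeric(noise_sd_rel),
         seed = as.integer(seed)),
    class = "acquisition_config"
  )
}

#' @rdname acquisition_config
#' @param ... Overrides passed on to [acquisition_config()].
#' @export
acquisition_config_coarse <- function(...) {
  defaults <- list(n_frames = 32L, dt_seconds = 7.7,
                   voxel_dims_mm = c(2, 2, 2), baseline_frames = 0L)
  args <- utils::modifyList(defaults, list(...))
  # the coarse dialect has fewer than baseline+32 frames by design: the
  # 32-point window is obtained after resampling, so relax that check here
  cfg <- do.call(acquisition_config_unchecked, args)
  cfg
}

acquisition_config_unchecked <- function(n_frames = 60L, dt_seconds = 3,
                                         voxel_dims_mm = c(1.56, 1.56, 1.5),
                                         baseline_frames = 10L,
                                         noise_sd_rel = 0.02, seed = 17L) {
  structure(
    list(n_frames = as.integer(n_frames),
         dt_seconds = as.numeric(dt_seconds),
         voxel_dims_mm = as.numeric(voxel_dims_mm),
         baseline_frames = as.integer(baseline_frames),
         noise_sd_rel = as.numeric(noise_sd_rel),
         seed = as.integer(seed)),
    class = "acquisition_config"
  )
}

#' Sample times of an acquisition
#'
#' Frame `k` is acquired at `(k - 1) * dt_seconds` seconds; the first frame
#' is at time 0.
#'
#' @param cfg An [acquisition_config()].
#' @return Numeric vector of length `n_frames`.
#' @export
acquisition_times <- function(cfg) {
  (seq_len(cfg$n_frames) - 1) * cfg$dt_seconds
}

#' Voxel volume in cubic millimetres
#' @param cfg An [acquisition_config()].
#' @return Scalar voxel volume (mm^3).
#' @export
voxel_volume_mm3 <- function(cfg) prod(cfg$voxel_dims_mm)

#' Analytic arterial input function model
#'
#' A parametric stand-in for a measured arterial input function: zero before
#' the bolus-arrival time, a gamma-variate first pass
#' `g(tau) = (tau / (alpha * beta))^alpha * exp(alpha - tau / beta)`
#' (unit peak at its mode `alpha * beta`), and after the peak a
#' mono-exponential washout towards a plateau that mimics the
#' contrast-agent steady state. The sampled curve is rescaled so its
#' maximum equals `peak_enhancement` exactly.
#'
#' @param onset_time_s Bolus arrival time in seconds (>= 0).
#' @param peak_enhancement Peak relative enhancement of the AIF (> 0); this
#'   is the `AIF_max` used to normalize tissue curves.
#' @param alpha,beta_s Gamma-variate shape and time-scale (seconds); the
#'   first-pass peak sits at `alpha * beta_s` seconds after onset.
#' @param washout_tau_s Washout time constant in seconds.
#' @param plateau_frac Asymptotic enhancement after washout, as a fraction
#'   of the peak (in `[0, 1)`).
#'
#' @return An object of class `aif_model`.
#' @export
aif_model <- function(onset_time_s = 30,
                      peak_enhancement = 2.5,
                      alpha = 3,
                      beta_s = 4,
                      washout_tau_s = 80,
                      plateau_frac = 0.3) {
  stopifnot(is.finite(onset_time_s), onset_time_s >= 0,
            is.finite(alpha), alpha > 0, is.finite(beta_s), beta_s > 0,
            is.finite(washout_tau_s), washout_tau_s > 0,
            is.finite(plateau_frac), plateau_frac >= 0, plateau_frac < 1)
  if (!is.finite(peak_enhancement) || peak_enhancement <= 0) {
    stop("aif_model: peak_enhancement must be a positive number", call. = FALSE)
  }
  structure(
    list(onset_time_s = as.numeric(onset_time_s),
         peak_enhancement = as.numeric(peak_enhancement),
         alpha = as.numeric(alpha),
         beta_s = as.numeric(beta_s),
         washout_tau_s = as.numeric(washout_tau_s),
         plateau_frac = as.numeric(plateau_frac)),
    class = "aif_model"
  )
}

# Unit-peak AIF shape as a function of time since onset (tau >= 0).
aif_shape <- function(model, tau) {
  t_peak <- model$alpha * model$beta_s
  out <- numeric(length(tau))
  rise <- tau >= 0 & tau <= t_peak
  out[rise] <- (tau[rise] / t_peak)^model$alpha *
    exp(model$alpha - tau[rise] / model$beta_s)
  fall <- tau > t_peak
  p <- model$plateau_frac
  out[fall] <- p + (1 - p) * exp(-(tau[fall] - t_peak) / model$washout_tau_s)
  out
}

#' Generate a sampled AIF enhancement curve
#'
#' Evaluates the analytic AIF model on the acquisition time grid. The
#' returned curve is zero strictly before the onset time and is normalized
#' so that its maximum equals `model$peak_enhancement`.
#'
#' @param model An [aif_model()].
#' @param cfg An [acquisition_config()].
#' @return Numeric enhancement curve of length `cfg$n_frames`.
#' @examples
#' curve <- generate_aif(aif_model(onset_time_s = 30), acquisition_config())
#' max(curve)   # == peak_enhancement
#' @export
generate_aif <- function(model, cfg) {
  stopifnot(inherits(model, "aif_model"), inherits(cfg, "acquisition_config"))
  times <- acquisition_times(cfg)
  if (model$onset_time_s >= max(times)) {
    stop("aif-onset-out-of-range: AIF onset (", model$onset_time_s,
         " s) lies at or beyond the scan duration (", max(times), " s)",
         call. = FALSE)
  }
  tau <- times - model$onset_time_s
  shape <- numeric(length(tau))
  on <- tau >= 0
  shape[on] <- aif_shape(model, tau[on])
  m <- max(shape)
  if (m <= 0) stop("aif-onset-out-of-range: no post-onset samples", call. = FALSE)
  model$peak_enhancement * shape / m
}
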