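#' Estimate the pre-contrast baseline signal
#'
#' The baseline `S0` is the arithmetic mean of the signal over the
#' pre-onset frames. At least 3 pre-onset frames are required for a stable
#' estimate.
#'
#' @param curve Raw signal-intensity curve.
#' @param pre_onset_frames Number of leading frames acquired before the
#'   contrast onset.
#' @return Scalar baseline `S0`.
#' @export
estimate_baseline <- function(curve, pre_onset_frames) {
  pre_onset_frames <- as.integer(pre_onset_frames)
  if (pre_onset_frames < 3L) {
    stop("estimate_baseline: at least 3 pre-onset frames are required",
         call. = FALSE)
  }
  stopifnot(pre_onset_frames <= length(curve))
  mean(curve[seq_len(pre_onset_frames)])
}

#' Normalize a signal curve to the AIF peak
#'
#' Converts raw signal to relative enhancement,
#' `dS(t) = (S(t) - S0) / S0`, and normalizes it to the peak enhancement of
#' the arterial input function: `dS_N(t) = dS(t) / AIF_max`. This removes
#' inter-patient variation in both signal scale and injected-bolus
#' magnitude.
#'
#' @param curve Raw signal curve (vector) or `n_vox x n_time` matrix.
#' @param s0 Baseline signal(s), scalar or one per row; must be positive.
#' @param aif_max Peak AIF enhancement (positive scalar).
#' @return Normalized enhancement, same shape as `curve`.
#' @export
normalize_curve <- function(curve, s0, aif_max) {
  if (!all(is.finite(aif_max)) || aif_max <= 0) {
    stop("normalize_curve: aif_max must be positive", call. = FALSE)
  }
  if (any(s0 <= .Machine$double.eps)) {
    stop("nonpositive-baseline: S0 must be positive", call. = FALSE)
  }
  ((curve - s0) / s0) / aif_max
}

#' Extract the arterial input function from an artery region
#'
#' Estimates each artery voxel's baseline from the leading
#' `baseline_frames` frames, converts to relative enhancement, ranks artery
#' voxels by their peak enhancement and averages the top `top_fraction`
#' most-enhancing voxels into a single AIF curve. The onset is the first
#' frame where the curve exceeds `onset_fraction` of its peak. Both the
#' onset index and the peak can be overridden manually, mirroring practice
#' where these two AIF parameters are read off by an operator.
#'
#' @param series 4D signal array (`x, y, z, t`).
#' @param artery_mask Logical 3D mask of the artery region.
#' @param baseline_frames Frames used for the artery baseline (>= 3).
#' @param top_fraction Fraction of most-enhancing artery voxels averaged
#'   (default 0.10).
#' @param onset_fraction Onset detector: first crossing of this fraction of
#'   the peak (default 0.10).
#' @param onset_index,peak_enhancement Optional manual overrides.
#' @return An object of class `dce_aif`: list with `curve` (enhancement
#'   series), `onset_index` (1-based frame) and `peak_enhancement`.
#' @export
extract_aif <- function(series, artery_mask, baseline_frames = 5L,
                        top_fraction = 0.10, onset_fraction = 0.10,
                        onset_index = NULL, peak_enhancement = NULL) {
  stopifnot(length(dim(series)) == 4L)
  idx <- which(artery_mask)
  if (length(idx) == 0L) stop("aif-not-found: artery mask is empty", call. = FALSE)
  n_t <- dim(series)[4]
  flat <- matrix(series, prod(dim(series)[1:3]), n_t)[idx, , drop = FALSE]
  s0 <- rowMeans(flat[, seq_len(max(3L, baseline_frames)), drop = FALSE])
  if (any(s0 <= .Machine$double.eps)) {
    stop("aif-not-found: nonpositive baseline in artery region", call. = FALSE)
  }
  enh <- (flat - s0) / s0
  peaks <- apply(enh, 1, max)
  n_top <- max(1L, ceiling(top_fraction * length(idx)))
  top <- order(peaks, decreasing = TRUE)[seq_len(n_top)]
  curve <- colMeans(enh[top, , drop = FALSE])
  pk <- max(curve)
  if (!is.finite(pk) || pk <= 1e-9) {
    stop("aif-not-found: artery region shows no enhancement", call. = FALSE)
  }
  onset <- if (is.null(onset_index)) {
    which(curve > onset_fraction * pk)[1]
  } else as.integer(onset_index)
  if (is.na(onset)) stop("aif-not-found: no onset crossing", call. = FALSE)
  if (!is.null(peak_enhancement)) pk <- as.numeric(peak_enhancement)
  structure(list(curve = curve, onset_index = onset, peak_enhancement = pk),
            class = "dce_aif")
}

#' @export
print.dce_aif <- function(x, ...) {
  cat("<dce_aif> ", length(x$curve), " frames, onset frame ", x$onset_index,
      ", peak enhancement ", signif(x$peak_enhancement, 4), "\n", sep = "")
  invisible(x)
}

#' Window a normalized curve to the 32-point dyadic segment
#'
#' Selects exactly `window_length` consecutive time points starting at the
#' AIF onset frame (inclusive). The dyadic default of 32 points captures
#' the initial enhancement and peak while dropping the pre-contrast
#' samples and the extended washout tail, and is the length the wavelet
#' feature extraction requires.
#'
#' @param curve Normalized enhancement series (vector) or matrix with time
#'   along columns.
#' @param onset_index 1-based frame index of the AIF onset.
#' @param window_length Window length (default 32).
#' @return The windowed values (vector or matrix with `window_length`
#'   columns).
#' @export
window_curve <- function(curve, onset_index, window_length = 32L) {
  n <- if (is.matrix(curve)) ncol(curve) else length(curve)
  onset_index <- as.integer(onset_index)
  stopifnot(onset_index >= 1L)
  if (onset_index + window_length - 1L > n) {
    stop("window-overrun: need ", window_length, " frames from onset ",
         onset_index, " but series has only ", n,
         " (resample to a finer grid first)", call. = FALSE)
  }
  cols <- onset_index:(onset_index + window_length - 1L)
  if (is.matrix(curve)) curve[, cols, drop = FALSE] else curve[cols]
}

#' Resample a curve onto a uniform time grid
#'
#' Linear interpolation of a uniformly sampled curve (spacing `dt_in`)
#' at times `k * dt_out`, `k = 0, 1, ...`, within the original span.
#' The output has `floor(span / dt_out) + 1` samples where
#' `span = (n - 1) * dt_in`. Used to map a coarse acquisition dialect
#' (e.g. 7.7 s) onto a grid close to the native training resolution.
#'
#' @param curve Numeric vector, or matrix with time along columns.
#' @param dt_in,dt_out Input and output sample spacings in seconds.
#' @return Resampled curve (vector or matrix).
#' @export
resample_curve <- function(curve, dt_in, dt_out) {
  stopifnot(dt_in > 0, dt_out > 0)
  n <- if (is.matrix(curve)) ncol(curve) else length(curve)
  span <- (n - 1) * dt_in
  if (dt_out >= span) {
    stop("resample_curve: dt_out (", dt_out, " s) must be smaller than the ",
         "series span (", span, " s)", call. = FALSE)
  }
  t_in <- (seq_len(n) - 1) * dt_in
  t_out <- seq(0, span, by = dt_out)
  if (is.matrix(curve)) {
    t(apply(curve, 1, function(row) stats::approx(t_in, row, xout = t_out)$y))
  } else {
    stats::approx(t_in, curve, xout = t_out)$y
  }
}

#' Resample a 4D series onto a uniform time grid
#'
#' Applies [resample_curve()] to every voxel of a 4D series.
#'
#' @param series 4D signal array (`x, y, z, t`).
#' @inheritParams resample_curve
#' @return 4D array on the new time grid.
#' @export
resample_series <- function(series, dt_in, dt_out) {
  stopifnot(length(dim(series)) == 4L)
  dm <- dim(series)
  flat <- matrix(series, prod(dm[1:3]), dm[4])
  out <- resample_curve(flat, dt_in, dt_out)
  array(out, c(dm[1:3], ncol(out)))
}

#' Preprocess a DCE series into normalized 32-point voxel windows
#'
#' Runs the full preprocessing chain for every tumor voxel: baseline
#' estimation over the pre-onset frames, enhancement normalization to the
#' AIF peak, and windowing to `window_length` points from the AIF onset.
#' Voxels with a nonpositive baseline are excluded (not imputed) and
#' reported in the `excluded` attribute.
#'
#' @param series 4D signal array.
#' @param tumor_mask Logical 3D mask of voxels to process.
#' @param aif A `dce_aif` (from [extract_aif()] or built manually).
#' @param window_length Window length (default 32).
#' @param min_baseline_frames Minimum pre-onset frames required (default 3).
#' @return A tibble with `voxel` (linear index into the 3D grid) and matrix
#'   column `window` (`n_vox x window_length`); attribute `excluded` lists
#'   dropped voxels and reasons.
#' @export
preprocess_series <- function(series, tumor_mask, aif, window_length = 32L,
                              min_baseline_frames = 3L) {
  stopifnot(length(dim(series)) == 4L, inherits(aif, "dce_aif"))
  n_pre <- aif$onset_index - 1L
  if (n_pre < min_baseline_frames) {
    stop("preprocess_series: only ", n_pre, " pre-onset frames available, ",
         "need at least ", min_baseline_frames, call. = FALSE)
  }
  idx <- which(tumor_mask)
  flat <- matrix(series, prod(dim(series)[1:3]), dim(series)[4])[idx, , drop = FALSE]
  s0 <- rowMeans(flat[, seq_len(n_pre), drop = FALSE])
  ok <- s0 > .Machine$double.eps
  excluded <- tibble::tibble(voxel = idx[!ok],
                             reason = rep("nonpositive-baseline", sum(!ok)))
  norm <- normalize_curve(flat[ok, , drop = FALSE], s0[ok],
                          aif$peak_enhancement)
  win <- window_curve(norm, aif$onset_index, window_length)
  out <- tibble::tibble(voxel = idx[ok], window = win)
  attr(out, "excluded") <- excluded
  out
}
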