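#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot normalized enhancement curves
#'
#' Spaghetti plot of a sample of voxel curves colored by class, with the
#' AIF overlaid, on the acquisition time axis.
#'
#' @param windows Matrix of windows (rows = voxels) or a tibble with
#'   matrix column `window`.
#' @param labels Optional class labels (0 = low BV, 1 = high BV).
#' @param dt_seconds Sample spacing for the time axis (default 3).
#' @param max_curves Number of curves drawn (sampled deterministically).
#' @return A ggplot object.
#' @export
plot_curves <- function(windows, labels = NULL, dt_seconds = 3,
                        max_curves = 100L) {
  x <- if (is.data.frame(windows)) windows$window else windows
  n <- nrow(x)
  keep <- if (n > max_curves) round(seq(1, n, length.out = max_curves)) else seq_len(n)
  df <- do.call(rbind, lapply(keep, function(i) {
    data.frame(voxel = i, t = (seq_len(ncol(x)) - 1) * dt_seconds,
               value = x[i, ],
               class = if (is.null(labels)) "voxel"
                       else ifelse(labels[i] == 0, "low BV", "high BV"))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   group = .data$voxel,
                                   color = .data$class)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "time since AIF onset (s)",
                  y = "normalized enhancement",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.dce_report
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.dce_prob_map <- function(object, slice = NULL, ...) {
  dm <- dim(object)
  if (is.null(slice)) slice <- which.max(apply(!is.nan(object), 3, sum))
  df <- expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]))
  df$p <- as.vector(object[, , slice])
  ggplot2::ggplot(df[!is.nan(df$p), ],
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "P(low BV)",
                  title = paste("posterior probability, slice", slice)) +
    ggplot2::theme_minimal()
}

#' Plot a pipeline report
#'
#' Shows the posterior low-BV probability map of the most tumor-dense
#' slice with the retained subvolume outlined.
#'
#' @param object A `dce_report` (or `dce_prob_map`).
#' @param slice Axial slice index; defaults to the slice with the most
#'   classified voxels.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.dce_report <- function(object, slice = NULL, ...) {
  p <- autoplot.dce_prob_map(object$prob_map, slice = slice)
  sub <- object$subvolume$mask
  if (is.null(slice)) slice <- which.max(apply(!is.nan(object$prob_map), 3, sum))
  dm <- dim(sub)
  df <- expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]))
  df$s <- as.vector(sub[, , slice])
  if (any(df$s)) {
    p <- p + ggplot2::geom_tile(data = df[df$s, ],
                                ggplot2::aes(x = .data$x, y = .data$y),
                                fill = NA, color = "red",
                                linewidth = 0.2, inherit.aes = FALSE)
  }
  p
}

#' Plot the AIF-sensitivity grid
#'
#' Accuracy of each onset-shift / peak-scale cell of the perturbation
#' grid.
#'
#' @param sensitivity Result of [run_aif_sensitivity()].
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(sensitivity) {
  ggplot2::ggplot(sensitivity,
                  ggplot2::aes(x = factor(.data$onset_shift),
                               y = .data$accuracy,
                               color = factor(.data$peak_scale),
                               group = factor(.data$peak_scale))) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "AIF onset shift (frames)", y = "accuracy (%)",
                  color = "AIF peak scale") +
    ggplot2::theme_minimal()
}
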