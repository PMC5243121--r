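#' Fit a principal-component basis to normalized windows
#'
#' Mean-centers the window matrix and computes all principal components of
#' the training curves. Components are sorted by decreasing explained
#' variance and given a deterministic sign: the loading with the largest
#' magnitude in each component is made positive, so a refit on identical
#' data reproduces the identical basis.
#'
#' @param windows `n x p` matrix of normalized windows (one row per voxel;
#'   `p` = 32 in the default pipeline), or a tibble with a matrix column
#'   `window`.
#' @return An object of class `dce_pca`: list with `mean` (length `p`),
#'   `rotation` (`p x p` orthonormal loadings), `sdev` and
#'   `var_explained` (fractions, non-increasing).
#' @export
fit_pca <- function(windows) {
  x <- if (is.data.frame(windows)) windows$window else windows
  stopifnot(is.matrix(x))
  if (nrow(x) < ncol(x)) {
    stop("insufficient-samples: need at least ", ncol(x),
         " windows to fit the full basis, got ", nrow(x), call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  # deterministic sign: largest-magnitude loading positive
  for (k in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, k]))
    if (rot[i, k] < 0) rot[, k] <- -rot[, k]
  }
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(mean = unname(pc$center),
                 rotation = unname(rot),
                 sdev = unname(pc$sdev),
                 var_explained = unname(var_frac)),
            class = "dce_pca")
}

#' @export
print.dce_pca <- function(x, ...) {
  cat("<dce_pca> ", ncol(x$rotation), " components over ",
      length(x$mean), "-point windows\n", sep = "")
  cum <- cumsum(x$var_explained)
  cat("  variance explained: PC1 ", round(100 * cum[1], 1), "%, PC1-2 ",
      round(100 * cum[2], 1), "%, PC1-4 ", round(100 * cum[4], 1), "%\n",
      sep = "")
  invisible(x)
}

#' Project windows onto the leading principal components
#'
#' Centers each window with the basis mean and projects it onto the first
#' `k` components; the projection coefficients are the PCA features of the
#' curve.
#'
#' @param windows Matrix of windows (rows = voxels) or a single window.
#' @param basis A [fit_pca()] result.
#' @param k Number of leading components (default 4).
#' @return `n x k` matrix of projection coefficients (columns `PC1..PCk`).
#' @export
project_pca <- function(windows, basis, k = 4L) {
  stopifnot(inherits(basis, "dce_pca"))
  k <- as.integer(k)
  if (k < 1L || k > ncol(basis$rotation)) {
    stop("project_pca: k must be between 1 and ", ncol(basis$rotation),
         call. = FALSE)
  }
  x <- if (is.matrix(windows)) windows else matrix(windows, nrow = 1)
  stopifnot(ncol(x) == length(basis$mean))
  out <- sweep(x, 2, basis$mean) %*% basis$rotation[, seq_len(k), drop = FALSE]
  colnames(out) <- paste0("PC", seq_len(k))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a principal-component basis
#'
#' One row per component with its standard deviation and the explained
#' variance fraction (and cumulative fraction).
#'
#' @param x A `dce_pca` object.
#' @param ... Unused.
#' @return A tibble with `component`, `sdev`, `var_explained`,
#'   `cum_var_explained`.
#' @exportS3Method generics::tidy
#' @export
tidy.dce_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$sdev),
                 sdev = x$sdev,
                 var_explained = x$var_explained,
                 cum_var_explained = cumsum(x$var_explained))
}
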