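#' Extract temporal features from preprocessed voxel windows
#'
#' Converts a table of normalized 32-point windows (as produced by
#' [preprocess_series()] or [phantom_curves()] after preprocessing) into a
#' per-voxel feature table, using either the full Haar wavelet
#' decomposition (`method = "wt"`, 32 coefficients) or projections onto a
#' principal-component basis (`method = "pca"`, `k` coefficients).
#'
#' @param windows A tibble with a matrix column `window` (and any
#'   identifier columns, which are carried through), or a plain matrix.
#' @param method `"wt"` or `"pca"`.
#' @param basis A [fit_pca()] basis (required for `method = "pca"`; if
#'   `NULL` one is fitted to `windows` and attached as attribute `basis`).
#' @param k Number of leading components for PCA features (default 4).
#' @return A tibble: identifier columns plus a matrix column `features`
#'   with named columns (Haar coefficient names or `PC1..PCk`).
#' @export
extract_features <- function(windows, method = c("wt", "pca"),
                             basis = NULL, k = 4L) {
  method <- match.arg(method)
  if (is.matrix(windows)) {
    windows <- tibble::tibble(voxel = seq_len(nrow(windows)), window = windows)
  }
  stopifnot(is.matrix(windows$window))
  x <- windows$window
  fitted_basis <- NULL
  feats <- if (method == "wt") {
    haar_full(x)
  } else {
    if (is.null(basis)) {
      basis <- fit_pca(x)
      fitted_basis <- basis
    }
    project_pca(x, basis, k = k)
  }
  out <- windows[setdiff(names(windows), "window")]
  out$features <- feats
  if (!is.null(fitted_basis)) attr(out, "basis") <- fitted_basis
  out
}

#' Select feature columns by global index
#'
#' Restricts the matrix column `features` of a feature table to the given
#' coefficient indices (1-based, in the canonical Haar/PC ordering).
#'
#' @param features A tibble with matrix column `features`.
#' @param indices Integer indices of the columns to keep.
#' @return The tibble with `features` restricted to `indices`.
#' @export
select_features <- function(features, indices) {
  stopifnot(is.matrix(features$features),
            all(indices >= 1L), all(indices <= ncol(features$features)))
  features$features <- features$features[, indices, drop = FALSE]
  features
}
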