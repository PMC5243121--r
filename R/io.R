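#' Write a phantom to NIfTI files with a JSON truth sidecar
#'
#' Writes the 4D series, tumor and artery masks, the ground-truth BV and
#' label maps as NIfTI, and a JSON sidecar with the acquisition
#' configuration, AIF parameters and seed.
#'
#' @param phantom A [generate_phantom()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named vector of the written paths.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "dce_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vd <- phantom$cfg$voxel_dims_mm
  wr <- function(x, name) {
    path <- file.path(dir, paste0(name, ".nii.gz"))
    img <- RNifti::asNifti(x * 1)  # logical -> numeric
    RNifti::pixdim(img) <- if (length(dim(x)) == 4L) {
      c(vd, phantom$cfg$dt_seconds)
    } else vd
    RNifti::writeNifti(img, path)
    path
  }
  paths <- c(
    series = wr(phantom$series, "series"),
    tumor_mask = wr(phantom$tumor_mask, "tumor_mask"),
    artery_mask = wr(phantom$artery_mask, "artery_mask"),
    bv_map = wr(ifelse(is.na(phantom$truth$bv_percent), -1,
                       phantom$truth$bv_percent), "bv_map"),
    label_map = wr(ifelse(is.na(phantom$truth$label), -1L,
                          phantom$truth$label), "label_map")
  )
  sidecar <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(cfg = unclass(phantom$cfg),
         aif_model = unclass(phantom$aif_model),
         s0 = phantom$s0,
         bv_threshold = phantom$bv_threshold,
         lbv_fraction = phantom$truth$lbv_fraction),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, truth = sidecar))
}

#' Read a 4D DCE series and masks from NIfTI files
#'
#' @param series_path Path to the 4D series NIfTI.
#' @param tumor_mask_path,artery_mask_path Optional mask paths.
#' @return A list with `series` (4D array), logical `tumor_mask` and
#'   `artery_mask` (or `NULL`), and `voxel_dims_mm`/`dt_seconds` read from
#'   the header.
#' @export
read_dce <- function(series_path, tumor_mask_path = NULL,
                     artery_mask_path = NULL) {
  img <- RNifti::readNifti(series_path)
  pd <- RNifti::pixdim(img)
  rd_mask <- function(p) {
    if (is.null(p)) return(NULL)
    array(as.array(RNifti::readNifti(p)) > 0.5, dim(img)[1:3])
  }
  list(series = array(as.array(img), dim(img)),
       tumor_mask = rd_mask(tumor_mask_path),
       artery_mask = rd_mask(artery_mask_path),
       voxel_dims_mm = pd[1:3],
       dt_seconds = if (length(pd) >= 4) pd[4] else NA_real_)
}

#' Write a 3D map as NIfTI
#'
#' @param map 3D array (`NaN`/`NA` stored as `-1`).
#' @param path Output path.
#' @param voxel_dims_mm Voxel dimensions for the header.
#' @return Invisibly, `path`.
#' @export
write_map <- function(map, path, voxel_dims_mm = c(1.56, 1.56, 1.5)) {
  x <- ifelse(is.na(map), -1, map)
  img <- RNifti::asNifti(x * 1)
  RNifti::pixdim(img) <- voxel_dims_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Save or load a trained classification model bundle
#'
#' The bundle is a single JSON file holding the standardization
#' statistics, calibration coefficients, selected feature indices, PCA
#' basis (when present) and the support-vector expansion of the decision
#' function, so a saved model can be reloaded and applied without
#' retraining.
#'
#' @param model A [train_svm()] fit.
#' @param path Output JSON path.
#' @param selected Integer indices of the selected features (within the
#'   full 32-coefficient vector).
#' @param method Feature method, `"wt"` or `"pca"`.
#' @param basis Optional [fit_pca()] basis for `method = "pca"`.
#' @return `write_model_bundle` invisibly returns `path`;
#'   `read_model_bundle` returns a list with `model`, `selected`, `method`
#'   and `basis`.
#' @export
write_model_bundle <- function(model, path, selected, method, basis = NULL) {
  stopifnot(inherits(model, "dce_svm"))
  sv <- model$fit
  bundle <- list(
    method = method,
    selected = selected,
    center = model$center,
    scale = model$scale,
    calib_coef = model$calib_coef,
    classes = model$classes,
    C = model$C, gamma = model$gamma, seed = model$seed,
    svm = list(SV = as.matrix(sv$SV), coefs = as.numeric(sv$coefs),
               rho = sv$rho, labels = sv$labels, nSV = sv$nSV),
    basis = if (!is.null(basis)) {
      list(mean = basis$mean, rotation = basis$rotation,
           sdev = basis$sdev, var_explained = basis$var_explained)
    }
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- if (length(b$basis$mean) > 0) {
    structure(list(mean = b$basis$mean,
                   rotation = matrix(unlist(b$basis$rotation),
                                     nrow = length(b$basis$mean)),
                   sdev = b$basis$sdev,
                   var_explained = b$basis$var_explained),
              class = "dce_pca")
  }
  sv_mat <- as.matrix(b$svm$SV)
  # rebuild a minimal decision-function evaluator compatible with
  # predict_proba: RBF expansion sum_i coefs_i K(sv_i, x) - rho
  model <- structure(
    list(fit = structure(list(SV = sv_mat, coefs = b$svm$coefs,
                              rho = b$svm$rho, gamma = b$gamma),
                         class = "dce_svm_raw"),
         center = b$center, scale = b$scale,
         calib_coef = b$calib_coef, classes = b$classes,
         C = b$C, gamma = b$gamma, seed = b$seed,
         n_train = NA_integer_, train_accuracy = NA_real_),
    class = "dce_svm")
  list(model = model, selected = b$selected, method = b$method,
       basis = basis)
}

# decision values for the JSON-restored raw SVM representation
#' @export
predict.dce_svm_raw <- function(object, newdata, decision.values = TRUE, ...) {
  d2 <- outer(rowSums(newdata^2), rowSums(object$SV^2), `+`) -
    2 * newdata %*% t(object$SV)
  dv <- exp(-object$gamma * d2) %*% object$coefs - object$rho
  out <- factor(ifelse(dv > 0, 0L, 1L))
  attr(out, "decision.values") <- dv
  out
}
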