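#' Pipeline configuration
#'
#' Collects the tunable parameters of every pipeline stage in one
#' serializable list. The defaults are the reference operating point of
#' the method: a 32-point window, BV threshold 7.6%, posterior threshold
#' 0.5, 1-cc minimum subvolume, RBF SVM with `C = 200` and
#' `gamma = 0.2`, and 4 principal components.
#'
#' @param ... Overrides of the defaults (see Details).
#' @details Keys: `window_length`, `bv_threshold`, `prob_threshold`,
#'   `min_volume_cc`, `connectivity`, `C`, `gamma`, `pca_k`,
#'   `aif_top_fraction`, `aif_onset_fraction`, `train_fraction`,
#'   `per_class_cap`, `resample_dt_out`, `seed`.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    window_length = 32L,
    bv_threshold = 7.6,
    prob_threshold = 0.5,
    min_volume_cc = 1.0,
    connectivity = 26L,
    C = 200,
    gamma = 0.2,
    pca_k = 4L,
    aif_top_fraction = 0.10,
    aif_onset_fraction = 0.10,
    train_fraction = 0.7,
    per_class_cap = 20000L,
    resample_dt_out = 4.1,
    seed = 1L
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  structure(utils::modifyList(cfg, over), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# Compute feature vectors for a set of windows under a trained feature
# recipe (method + selected indices + optional PCA basis).
featurize <- function(windows, method, selected, basis, pca_k) {
  x <- if (is.data.frame(windows)) windows$window else windows
  if (method == "wt") {
    haar_full(x)[, selected, drop = FALSE]
  } else {
    project_pca(x, basis, k = pca_k)[, selected, drop = FALSE]
  }
}

# Classify every preprocessed tumor voxel of a series with a trained
# model; returns tibble (voxel, p_lbv, label_pred).
classify_series <- function(series, tumor_mask, aif, classifier, config) {
  win <- preprocess_series(series, tumor_mask, aif,
                           window_length = config$window_length)
  feats <- featurize(win, classifier$method, classifier$selected,
                     classifier$basis,
                     pca_k = max(classifier$selected))
  p <- predict_proba(classifier$model, feats)
  tibble::tibble(voxel = win$voxel, p_lbv = p,
                 label_pred = assign_labels(p, config$prob_threshold))
}

#' Run the full training + evaluation pipeline on a phantom
#'
#' Executes the five pipeline stages end to end on a digital phantom:
#' AIF extraction from the artery region, preprocessing of all tumor
#' voxels into normalized 32-point windows, temporal feature extraction
#' (Haar wavelet with CFS/best-first subset selection, or PCA with top-k
#' components), SVM training on a seeded 70/30 curve-level split, and
#' probability-map / subvolume assembly with the minimum-volume filter.
#' Accuracy is evaluated on the held-out 30%; the Dice coefficient
#' compares the assembled low-BV subvolume against the ground-truth
#' subvolume, with the same minimum-volume filter applied to both masks.
#'
#' Training labels come from the phantom's constructed truth by default;
#' `labels = "pk"` instead re-derives them by voxelwise Tofts fitting
#' (the slower two-step reference pathway).
#'
#' @param phantom A [generate_phantom()] result.
#' @param mode `"wt"` (Haar + CFS subset) or `"pca"` (top-k projections).
#' @param config A [pipeline_config()].
#' @param labels `"truth"` or `"pk"`.
#' @return An object of class `dce_report`; see [glance.dce_report()].
#' @export
run_pipeline <- function(phantom, mode = c("wt", "pca"),
                         config = pipeline_config(),
                         labels = c("truth", "pk")) {
  mode <- match.arg(mode)
  labels <- match.arg(labels)
  stopifnot(inherits(phantom, "dce_phantom"))

  aif <- extract_aif(phantom$series, phantom$artery_mask,
                     baseline_frames = max(3L, phantom$cfg$baseline_frames),
                     top_fraction = config$aif_top_fraction,
                     onset_fraction = config$aif_onset_fraction)
  win <- preprocess_series(phantom$series, phantom$tumor_mask, aif,
                           window_length = config$window_length)

  y <- if (labels == "truth") {
    phantom$truth$label[win$voxel]
  } else {
    times <- acquisition_times(phantom$cfg)
    dm <- dim(phantom$series)
    flat <- matrix(phantom$series, prod(dm[1:3]), dm[4])
    s0 <- rowMeans(flat[win$voxel, seq_len(aif$onset_index - 1L), drop = FALSE])
    norm <- normalize_curve(flat[win$voxel, , drop = FALSE], s0,
                            aif$peak_enhancement)
    fit_bv(norm, aif$curve / aif$peak_enhancement, times,
           bv_threshold = config$bv_threshold)$label
  }

  # seeded 70/30 split at curve (voxel) level
  n <- nrow(win)
  idx_train <- with_seed(config$seed,
                         sort(sample(n, round(config$train_fraction * n))))
  idx_test <- setdiff(seq_len(n), idx_train)

  basis <- NULL
  if (mode == "wt") {
    all_coef <- haar_full(win$window)
    subset <- best_first_search(all_coef[idx_train, , drop = FALSE],
                                y[idx_train])
    selected <- subset$indices
    feats <- all_coef[, selected, drop = FALSE]
  } else {
    basis <- fit_pca(win$window[idx_train, , drop = FALSE])
    selected <- select_top_pcs(basis, config$pca_k)
    feats <- project_pca(win$window, basis, k = config$pca_k)
    subset <- NULL
  }

  model <- train_svm(feats[idx_train, , drop = FALSE], y[idx_train],
                     C = config$C, gamma = config$gamma,
                     seed = config$seed,
                     per_class_cap = config$per_class_cap)
  classifier <- list(model = model, method = mode, selected = selected,
                     basis = basis)

  p_all <- predict_proba(model, feats)
  pred_all <- assign_labels(p_all, config$prob_threshold)
  holdout_acc <- voxel_accuracy(pred_all[idx_test], y[idx_test])
  overall_acc <- voxel_accuracy(pred_all, y)

  prob_map <- assemble_maps(p_all, win$voxel, phantom$tumor_mask)
  sub_pred <- extract_subvolume(prob_map, threshold = config$prob_threshold,
                                min_volume_cc = config$min_volume_cc,
                                connectivity = config$connectivity,
                                voxel_dims_mm = phantom$cfg$voxel_dims_mm)
  truth_lbv <- !is.na(phantom$truth$label) & phantom$truth$label == 0L
  sub_truth <- extract_subvolume(truth_lbv,
                                 min_volume_cc = config$min_volume_cc,
                                 connectivity = config$connectivity,
                                 voxel_dims_mm = phantom$cfg$voxel_dims_mm)
  dsc_lbv <- dice(sub_truth, sub_pred)
  # correctly classified voxels (low + high BV) against the full tumor
  correct <- array(FALSE, dim(phantom$tumor_mask))
  correct[win$voxel[pred_all == y]] <- TRUE
  dsc_lbv_hbv <- dice(correct, phantom$tumor_mask)

  structure(
    list(mode = mode, config = config, aif = aif,
         classifier = classifier, subset = subset,
         voxel = win$voxel, labels = y, p_lbv = p_all,
         label_pred = pred_all,
         idx_train = idx_train, idx_test = idx_test,
         prob_map = prob_map, subvolume = sub_pred,
         subvolume_truth = sub_truth,
         metrics = tibble::tibble(
           mode = mode,
           n_voxels = n,
           n_train = length(idx_train),
           n_test = length(idx_test),
           holdout_accuracy = holdout_acc,
           overall_accuracy = overall_acc,
           dsc_lbv = dsc_lbv,
           dsc_lbv_hbv = dsc_lbv_hbv,
           slbv_fraction = sum(sub_pred$mask) / sum(phantom$tumor_mask))),
    class = "dce_report"
  )
}

#' @export
print.dce_report <- function(x, ...) {
  m <- x$metrics
  cat("<dce_report> mode = ", x$mode, ", ", m$n_voxels, " voxels (",
      m$n_train, " train / ", m$n_test, " test)\n", sep = "")
  cat("  held-out accuracy: ", round(m$holdout_accuracy, 1), "%",
      "   DSC (s-LBV): ", round(m$dsc_lbv, 3),
      "   DSC (LBV+HBV): ", round(m$dsc_lbv_hbv, 3), "\n", sep = "")
  if (!is.null(x$subset)) {
    cat("  selected coefficients: ",
        paste(x$subset$indices, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Metric summary of a pipeline report
#'
#' @param x A `dce_report`.
#' @param ... Unused.
#' @return One-row tibble of the report metrics.
#' @exportS3Method generics::glance
#' @export
glance.dce_report <- function(x, ...) x$metrics

#' Write the metric report as JSON
#'
#' @param report A `dce_report`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(as.list(report$metrics), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Apply a trained classifier to a new series (usage phase)
#'
#' The usage phase runs preprocessing, feature extraction with the frozen
#' recipe, classification and subvolume assembly only -- no
#' pharmacokinetic fitting and no SVM training.
#'
#' @param series 4D signal array.
#' @param tumor_mask Logical 3D tumor mask.
#' @param aif A `dce_aif` for this series.
#' @param classifier A classifier recipe: list with `model`, `method`,
#'   `selected`, `basis` (as in a `dce_report` or [read_model_bundle()]).
#' @param config A [pipeline_config()].
#' @param reference Optional reference label vector or 3D label map for
#'   accuracy/DSC evaluation.
#' @param voxel_dims_mm Voxel dimensions for the volume filter.
#' @return A list with `predictions` (tibble), `prob_map`, `subvolume`
#'   and, when a reference is given, `metrics`.
#' @export
predict_series <- function(series, tumor_mask, aif, classifier, config,
                           reference = NULL,
                           voxel_dims_mm = c(1.56, 1.56, 1.5)) {
  pred <- classify_series(series, tumor_mask, aif, classifier, config)
  prob_map <- assemble_maps(pred$p_lbv, pred$voxel, tumor_mask)
  sub <- extract_subvolume(prob_map, threshold = config$prob_threshold,
                           min_volume_cc = config$min_volume_cc,
                           connectivity = config$connectivity,
                           voxel_dims_mm = voxel_dims_mm)
  out <- list(predictions = pred, prob_map = prob_map, subvolume = sub)
  if (!is.null(reference)) {
    ref <- if (is.array(reference)) reference[pred$voxel] else reference
    out$metrics <- tibble::tibble(
      accuracy = voxel_accuracy(pred$label_pred, ref),
      n_voxels = nrow(pred))
  }
  out
}

#' AIF-parameter sensitivity experiment
#'
#' Re-normalizes and re-windows the series under perturbed AIF parameters
#' -- onset shifted by whole frames and peak enhancement scaled -- then
#' re-classifies with the trained model and reports the voxel accuracy of
#' every cell of the perturbation grid (default 5 onsets x 3 peaks). A
#' perturbation that pushes the window past the end of the series marks
#' the cell invalid (`NA` accuracy).
#'
#' @param phantom A [generate_phantom()] result (provides truth labels).
#' @param classifier A classifier recipe (see [predict_series()]).
#' @param config A [pipeline_config()].
#' @param onset_shifts Integer frame shifts (default `-2:2`).
#' @param peak_scales Multiplicative peak perturbations (default
#'   `c(0.9, 1, 1.1)`).
#' @return A tibble with `onset_shift`, `peak_scale`, `valid`, `accuracy`
#'   (percent; `NA` for invalid cells).
#' @export
run_aif_sensitivity <- function(phantom, classifier,
                                config = pipeline_config(),
                                onset_shifts = -2:2,
                                peak_scales = c(0.9, 1.0, 1.1)) {
  stopifnot(inherits(phantom, "dce_phantom"))
  aif0 <- extract_aif(phantom$series, phantom$artery_mask,
                      baseline_frames = max(3L, phantom$cfg$baseline_frames),
                      top_fraction = config$aif_top_fraction,
                      onset_fraction = config$aif_onset_fraction)
  grid <- expand.grid(onset_shift = as.integer(onset_shifts),
                      peak_scale = peak_scales)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    aif <- aif0
    aif$onset_index <- aif0$onset_index + grid$onset_shift[i]
    aif$peak_enhancement <- aif0$peak_enhancement * grid$peak_scale[i]
    pred <- tryCatch(
      classify_series(phantom$series, phantom$tumor_mask, aif, classifier,
                      config),
      error = function(e) NULL)
    if (is.null(pred)) return(c(valid = FALSE, accuracy = NA_real_))
    acc <- voxel_accuracy(pred$label_pred,
                          phantom$truth$label[pred$voxel])
    c(valid = TRUE, accuracy = acc)
  })
  out <- tibble::as_tibble(grid)
  out$valid <- vapply(res, function(r) as.logical(r[["valid"]]), logical(1))
  out$accuracy <- vapply(res, `[[`, numeric(1), "accuracy")
  out
}

#' Cross-dialect robustness experiment
#'
#' Renders the phantom's ground truth under a coarser acquisition dialect,
#' resamples the curves back to a near-native temporal resolution by
#' linear interpolation, and applies a classifier trained on the native
#' dialect without retraining.
#'
#' @param coarse_phantom A phantom generated with a coarse
#'   [acquisition_config()] (e.g. [acquisition_config_coarse()]).
#' @param classifier A classifier recipe trained on the native dialect.
#' @param config A [pipeline_config()]; `resample_dt_out` sets the target
#'   temporal resolution in seconds.
#' @return A list with `metrics` (tibble: accuracy, n_voxels, dt_out,
#'   n_frames_resampled) and the `predictions` tibble.
#' @export
run_robustness <- function(coarse_phantom, classifier,
                           config = pipeline_config()) {
  stopifnot(inherits(coarse_phantom, "dce_phantom"))
  rs <- resample_series(coarse_phantom$series,
                        dt_in = coarse_phantom$cfg$dt_seconds,
                        dt_out = config$resample_dt_out)
  aif <- extract_aif(rs, coarse_phantom$artery_mask,
                     baseline_frames = 3L,
                     top_fraction = config$aif_top_fraction,
                     onset_fraction = config$aif_onset_fraction)
  pred <- classify_series(rs, coarse_phantom$tumor_mask, aif, classifier,
                          config)
  acc <- voxel_accuracy(pred$label_pred,
                        coarse_phantom$truth$label[pred$voxel])
  list(metrics = tibble::tibble(accuracy = acc, n_voxels = nrow(pred),
                                dt_out = config$resample_dt_out,
                                n_frames_resampled = dim(rs)[4]),
       predictions = pred)
}
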