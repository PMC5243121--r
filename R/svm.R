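# Decision values of an e1071 svm on pre-standardized features, oriented
# so that larger values mean "more like the model's first factor level".
svm_decision <- function(fit, x) {
  pr <- stats::predict(fit, x, decision.values = TRUE)
  as.numeric(attr(pr, "decision.values"))
}

#' Train the low/high blood-volume SVM classifier
#'
#' Fits a soft-margin RBF-kernel support vector machine (libsvm) on
#' standardized feature vectors with the regularization and kernel
#' parameters of the voxel-classification model (`C = 200`,
#' `gamma = 0.2`). Posterior class probabilities are obtained by a
#' Platt-type sigmoid fitted to cross-validated decision values: the
#' training set is split into `calib_folds` seeded folds, a fold-withheld
#' SVM produces out-of-fold decision values, and a logistic regression of
#' the class indicator on those values maps decision values to
#' `P(low BV)`. Large training sets are stratified-subsampled to at most
#' `per_class_cap` curves per class with the given seed.
#'
#' @param features `n x k` feature matrix, or a tibble with matrix column
#'   `features` and a `label` column.
#' @param labels Binary labels, 0 = low BV, 1 = high BV (ignored when
#'   `features` is a tibble carrying `label`).
#' @param C Misclassification cost (default 200).
#' @param gamma RBF kernel width parameter (default 0.2).
#' @param seed Seed for subsampling and calibration folds.
#' @param per_class_cap Maximum training curves per class (default 20000).
#' @param calib_folds Cross-validation folds for the sigmoid calibration
#'   (default 5).
#' @param class_weights Optional named class weights passed to the solver
#'   (default none).
#' @return An object of class `dce_svm` holding the fitted SVM, the
#'   standardization statistics, the calibration coefficients and the
#'   training metadata.
#' @export
train_svm <- function(features, labels = NULL, C = 200, gamma = 0.2,
                      seed = 1L, per_class_cap = 20000L, calib_folds = 5L,
                      class_weights = NULL) {
  if (is.data.frame(features)) {
    labels <- features$label
    features <- features$features
  }
  stopifnot(is.matrix(features), length(labels) == nrow(features))
  y <- as.integer(labels)
  classes <- sort(unique(y))
  if (length(classes) != 2L) {
    stop("degenerate-labels: training data must contain both classes",
         call. = FALSE)
  }

  with_seed(seed, {
    keep <- unlist(lapply(classes, function(cl) {
      i <- which(y == cl)
      if (length(i) > per_class_cap) sample(i, per_class_cap) else i
    }))
    keep <- sort(keep)
    x <- features[keep, , drop = FALSE]
    yk <- y[keep]

    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
    xs <- scale(x, center = center, scale = scale_)

    yf <- factor(yk, levels = classes)
    fit <- e1071::svm(xs, yf, type = "C-classification", kernel = "radial",
                      cost = C, gamma = gamma, scale = FALSE,
                      class.weights = class_weights)

    # cross-validated decision values for Platt calibration
    folds <- sample(rep_len(seq_len(calib_folds), length(yk)))
    dv <- numeric(length(yk))
    for (f in seq_len(calib_folds)) {
      tr <- folds != f
      if (length(unique(yk[tr])) < 2L) next
      cv_fit <- e1071::svm(xs[tr, , drop = FALSE], yf[tr],
                           type = "C-classification", kernel = "radial",
                           cost = C, gamma = gamma, scale = FALSE,
                           class.weights = class_weights)
      dv[!tr] <- svm_decision(cv_fit, xs[!tr, , drop = FALSE])
    }
    is_lbv <- as.integer(yk == classes[1])   # class "0" = low BV
    # separable training data give a divergent (perfect) sigmoid; that is
    # fine for prediction, so silence glm's separation warning
    calib <- suppressWarnings(
      stats::glm(is_lbv ~ dv, family = stats::binomial()))
    train_dv <- svm_decision(fit, xs)
  }) -> train_dv

  structure(
    list(fit = fit, center = center, scale = scale_,
         calib_coef = unname(stats::coef(calib)),
         classes = classes, C = C, gamma = gamma, seed = seed,
         n_train = length(yk), n_per_class = table(yk),
         train_accuracy = mean(
           ifelse(stats::plogis(cbind(1, train_dv) %*%
                                  stats::coef(calib)) > 0.5,
                  classes[1], classes[2]) == yk) * 100),
    class = "dce_svm"
  )
}

#' @export
print.dce_svm <- function(x, ...) {
  cat("<dce_svm> RBF SVM, C = ", x$C, ", gamma = ", x$gamma,
      ", ", x$n_train, " training curves, ",
      x$fit$tot.nSV, " support vectors\n", sep = "")
  cat("  training accuracy: ", round(x$train_accuracy, 1), "%\n", sep = "")
  invisible(x)
}

#' Posterior probability of the low blood-volume class
#'
#' Standardizes the input features with the training statistics, evaluates
#' the SVM decision function and maps it through the fitted Platt sigmoid.
#' Probabilities of the two classes sum to one by construction.
#'
#' @param model A [train_svm()] fit.
#' @param features `m x k` feature matrix (or tibble with matrix column
#'   `features`), `k` matching the training dimension.
#' @return Numeric vector of `P(low BV)` in `[0, 1]`.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "dce_svm"))
  if (is.data.frame(features)) features <- features$features
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(model$center)) {
    stop("predict_proba: feature dimension ", ncol(features),
         " does not match the model (", length(model$center), ")",
         call. = FALSE)
  }
  xs <- scale(features, center = model$center, scale = model$scale)
  dv <- svm_decision(model$fit, xs)
  as.numeric(stats::plogis(model$calib_coef[1] + model$calib_coef[2] * dv))
}

#' Assign class labels from posterior probabilities
#'
#' A voxel is assigned the low-BV class when its posterior probability is
#' strictly greater than the threshold; a probability exactly at the
#' threshold is assigned high BV.
#'
#' @param probabilities `P(low BV)` values in `[0, 1]`.
#' @param threshold Assignment threshold (default 0.5).
#' @return Integer labels: 0 (low BV) where `p > threshold`, else 1.
#' @examples
#' assign_labels(c(0, 0.5, 0.500001, 1))   # 1 1 0 0
#' @export
assign_labels <- function(probabilities, threshold = 0.5) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1, na.rm = TRUE))
  ifelse(probabilities > threshold, 0L, 1L)
}

#' @rdname train_svm
#' @param x A `dce_svm` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
#' @export
glance.dce_svm <- function(x, ...) {
  tibble::tibble(n_train = x$n_train,
                 n_support_vectors = x$fit$tot.nSV,
                 C = x$C, gamma = x$gamma, seed = x$seed,
                 train_accuracy = x$train_accuracy)
}
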