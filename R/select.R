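# Absolute Pearson correlations used by the CFS merit. A zero-variance
# column correlates 0 with everything by convention.
abs_cor_safe <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) return(0)
  abs(stats::cor(a, b))
}

#' Correlation-based feature subset merit
#'
#' Hall's CFS merit of a feature subset:
#' `M = k * rcf / sqrt(k + k * (k - 1) * rff)` where `rcf` is the mean
#' absolute feature-class correlation of the subset and `rff` the mean
#' absolute pairwise correlation between its features. Subsets of features
#' that each track the class but not one another score highest; adding a
#' redundant copy of a feature never raises the merit. Correlations are
#' Pearson (point-biserial against the binary class); zero-variance
#' features contribute zero correlation.
#'
#' @param indices Feature column indices of the subset (nonempty).
#' @param features `n x p` feature matrix.
#' @param labels Binary labels (length `n`, two levels).
#' @return The scalar merit.
#' @examples
#' x <- cbind(a = rnorm(50), b = rnorm(50))
#' y <- rep(0:1, each = 25)
#' cfs_merit(1, x, y)   # == |cor(x[,1], y)|
#' @export
cfs_merit <- function(indices, features, labels) {
  stopifnot(length(indices) >= 1L)
  y <- as.numeric(as.factor(labels))
  if (length(unique(y)) != 2L) {
    stop("cfs_merit: labels must have exactly two classes", call. = FALSE)
  }
  k <- length(indices)
  rcf <- mean(vapply(indices, function(i) abs_cor_safe(features[, i], y),
                     numeric(1)))
  if (k == 1L) return(rcf)
  pairs <- utils::combn(indices, 2)
  rff <- mean(vapply(seq_len(ncol(pairs)), function(j) {
    abs_cor_safe(features[, pairs[1, j]], features[, pairs[2, j]])
  }, numeric(1)))
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

# Shared machinery: evaluate-with-cache, deterministic lowest-index
# tie-break on equal merit.
subset_key <- function(idx) paste(sort(idx), collapse = ",")

# Precompute the absolute correlation structure once so the searches score
# subsets in O(k^2) arithmetic instead of repeated cor() calls.
cfs_tables <- function(features, labels) {
  y <- as.numeric(as.factor(labels))
  if (length(unique(y)) != 2L) {
    stop("cfs: labels must have exactly two classes", call. = FALSE)
  }
  p <- ncol(features)
  sds <- apply(features, 2, stats::sd)
  ok <- is.finite(sds) & sds > 0
  rcf <- numeric(p)
  rcf[ok] <- abs(stats::cor(features[, ok, drop = FALSE], y))
  rff <- matrix(0, p, p)
  if (any(ok)) {
    rff[ok, ok] <- abs(stats::cor(features[, ok, drop = FALSE]))
  }
  diag(rff) <- 1
  list(rcf = rcf, rff = rff)
}

merit_from_tables <- function(idx, tb) {
  k <- length(idx)
  rcf <- mean(tb$rcf[idx])
  if (k == 1L) return(rcf)
  rff <- (sum(tb$rff[idx, idx]) - k) / (k * (k - 1))
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Best-first search for a high-merit feature subset
#'
#' Forward best-first search over feature subsets scored by [cfs_merit()]:
#' starting from the empty set, the open list always expands the
#' highest-merit subset seen so far by one feature, and the search stops
#' after `stall_limit` consecutive expansions that fail to improve the best
#' merit. Ties are broken toward the lower feature index, making the
#' search fully deterministic.
#'
#' @param features `n x p` feature matrix (standardization does not change
#'   Pearson correlations, so raw or z-scored input give the same result).
#' @param labels Binary labels.
#' @param stall_limit Consecutive non-improving expansions tolerated
#'   (default 5).
#' @return A list of class `feature_subset` with sorted `indices` and
#'   `merit`.
#' @export
best_first_search <- function(features, labels, stall_limit = 5L) {
  p <- ncol(features)
  stopifnot(p >= 2L)
  tb <- cfs_tables(features, labels)
  merit_of <- function(idx) merit_from_tables(idx, tb)

  open <- list(list(indices = integer(0), merit = -Inf))
  expanded <- character(0)
  best <- open[[1]]
  stalls <- 0L
  while (length(open) > 0L && stalls < stall_limit) {
    # pop the best open node (ties: smallest first index, then shortest)
    merits <- vapply(open, `[[`, numeric(1), "merit")
    pick <- which.max(merits)
    node <- open[[pick]]
    open[[pick]] <- NULL
    key <- subset_key(node$indices)
    if (key %in% expanded) next
    expanded <- c(expanded, key)

    improved <- FALSE
    for (f in setdiff(seq_len(p), node$indices)) {
      child_idx <- sort(c(node$indices, f))
      ckey <- subset_key(child_idx)
      if (ckey %in% expanded) next
      m <- merit_of(child_idx)
      open[[length(open) + 1L]] <- list(indices = child_idx, merit = m)
      if (m > best$merit + 1e-12) {
        best <- list(indices = child_idx, merit = m)
        improved <- TRUE
      }
    }
    stalls <- if (improved) 0L else stalls + 1L
  }
  structure(list(indices = best$indices, merit = best$merit,
                 search = "best-first"),
            class = "feature_subset")
}

#' Greedy forward (stepwise) feature selection
#'
#' Forward stepwise search: at each step add the single feature whose
#' addition raises the [cfs_merit()] the most; stop as soon as no addition
#' improves it. Ties break toward the lower index.
#'
#' @inheritParams best_first_search
#' @return A `feature_subset` as in [best_first_search()].
#' @export
greedy_forward_search <- function(features, labels) {
  p <- ncol(features)
  stopifnot(p >= 2L)
  tb <- cfs_tables(features, labels)
  current <- integer(0)
  current_merit <- -Inf
  repeat {
    cand <- setdiff(seq_len(p), current)
    if (length(cand) == 0L) break
    merits <- vapply(cand, function(f) {
      merit_from_tables(sort(c(current, f)), tb)
    }, numeric(1))
    i <- which.max(merits)   # which.max returns the first (lowest index) tie
    if (merits[i] > current_merit + 1e-12) {
      current <- sort(c(current, cand[i]))
      current_merit <- merits[i]
    } else break
  }
  structure(list(indices = current, merit = current_merit,
                 search = "greedy-forward"),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat("<feature_subset> (", x$search, ") indices: ",
      paste(x$indices, collapse = ", "),
      "  merit: ", signif(x$merit, 4), "\n", sep = "")
  invisible(x)
}

#' Select the leading principal components
#'
#' PCA features are selected by eigenvalue: the first `k` components
#' (largest explained variance) are kept.
#'
#' @param basis A [fit_pca()] result.
#' @param k Number of components (default 4).
#' @return Integer vector `1:k`.
#' @export
select_top_pcs <- function(basis, k = 4L) {
  stopifnot(inherits(basis, "dce_pca"))
  k <- as.integer(k)
  if (k < 1L || k > ncol(basis$rotation)) {
    stop("select_top_pcs: k must be between 1 and ", ncol(basis$rotation),
         call. = FALSE)
  }
  seq_len(k)
}
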