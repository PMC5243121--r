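#' Names of the Haar coefficients in canonical order
#'
#' The canonical ordering is `[A_J, D_J, D_{J-1}, ..., D_1]` with each
#' detail block time-ascending; for a 32-point window (`J = 5`) the global
#' indices are 1 = `A5`, 2 = `D5`, 3-4 = `D4`, 5-8 = `D3`, 9-16 = `D2`,
#' 17-32 = `D1`.
#'
#' @param n Window length (power of 2).
#' @return Character vector of coefficient names, e.g. `"A5"`, `"D3.2"`.
#' @export
haar_coef_names <- function(n = 32L) {
  J <- as.integer(round(log2(n)))
  nm <- paste0("A", J)
  for (j in J:1) {
    k <- 2^(J - j)
    nm <- c(nm, if (k == 1) paste0("D", j) else paste0("D", j, ".", seq_len(k)))
  }
  nm
}

check_dyadic <- function(n) {
  J <- round(log2(n))
  if (n < 2 || 2^J != n) {
    stop("non-dyadic: window length must be a power of 2, got ", n,
         call. = FALSE)
  }
  as.integer(J)
}

#' Full Haar wavelet decomposition of a dyadic window
#'
#' Iteratively replaces pairs of adjacent samples by their average
#' (approximation) and half-difference (detail), `J = log2(N)` times,
#' yielding one approximation coefficient `A_J` and `N - 1` detail
#' coefficients arranged `[A_J, D_J, ..., D_1]` with each scale block
#' time-ascending. With the averaging convention `A_J` equals the mean of
#' the window, i.e. it is proportional to the area under the curve
#' (`AUC / 2^J` up to the sample spacing); the orthonormal `sqrt(2)`
#' convention is available via `normalization = "orthonormal"`, which
#' rescales each coefficient by a scale-dependent diagonal factor.
#'
#' @param window Numeric vector whose length is a power of 2, or a matrix
#'   (voxels in rows) with a dyadic number of columns.
#' @param normalization `"average"` (default; pair average / half
#'   difference) or `"orthonormal"` (`1/sqrt(2)` filters).
#' @return Named coefficient vector (or matrix) in canonical order.
#' @examples
#' haar_full(rep(3, 32))[1]   # A5 = 3, all details 0
#' @export
haar_full <- function(window, normalization = c("average", "orthonormal")) {
  normalization <- match.arg(normalization)
  if (is.matrix(window)) {
    out <- t(apply(window, 1, haar_full, normalization = normalization))
    colnames(out) <- haar_coef_names(ncol(window))
    return(out)
  }
  n <- length(window)
  J <- check_dyadic(n)
  s <- if (normalization == "average") 0.5 else 1 / sqrt(2)
  a <- window
  details <- vector("list", J)
  for (j in seq_len(J)) {
    odd <- a[seq(1, length(a), by = 2)]
    even <- a[seq(2, length(a), by = 2)]
    details[[j]] <- s * (odd - even)   # detail at scale level j
    a <- s * (odd + even)
  }
  out <- c(a, unlist(rev(details)))
  names(out) <- haar_coef_names(n)
  out
}

#' Inverse Haar transform
#'
#' Exact inverse of [haar_full()]: reconstructs the window from a
#' coefficient vector in canonical order.
#'
#' @param coefficients Coefficient vector of dyadic length in canonical
#'   order.
#' @inheritParams haar_full
#' @return The reconstructed window.
#' @export
haar_inverse <- function(coefficients, normalization = c("average", "orthonormal")) {
  normalization <- match.arg(normalization)
  n <- length(coefficients)
  J <- check_dyadic(n)
  inv <- if (normalization == "average") 1 else 1 / sqrt(2)
  a <- coefficients[1]
  pos <- 2L
  for (j in J:1) {
    k <- 2^(J - j)
    d <- coefficients[pos:(pos + k - 1L)]
    pos <- pos + k
    next_a <- numeric(2 * k)
    next_a[seq(1, 2 * k, by = 2)] <- inv * (a + d)
    next_a[seq(2, 2 * k, by = 2)] <- inv * (a - d)
    a <- next_a
  }
  unname(a)
}
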