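# Shared, lazily built fixtures. Phantoms and trained pipelines are
# deterministic for a fixed config, so they are computed once per session
# and reused across test files.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- make()
  .fixture_cache[[name]]
}

phantom_fix <- function(noise = 0.02, small = FALSE, coarse = FALSE) {
  name <- paste0("ph_", noise, "_", small, "_", coarse)
  fixture(name, function() {
    cfg <- if (coarse) {
      acquisition_config_coarse(noise_sd_rel = noise, seed = 17L)
    } else {
      acquisition_config(noise_sd_rel = noise, seed = 17L)
    }
    geo <- if (small) phantom_geometry_small() else phantom_geometry()
    generate_phantom(cfg, geometry = geo)
  })
}

report_fix <- function(mode, noise = 0.02) {
  fixture(paste0("rep_", mode, "_", noise), function() {
    run_pipeline(phantom_fix(noise), mode = mode)
  })
}

# Independent Haar analysis-matrix oracle, built directly from the
# block-mean definition of the coefficients (not from the iterative
# transform): A_J row = 1/N; the detail d_j^i row is +1/2^j over the first
# half of block i at scale j and -1/2^j over the second half; rows in
# canonical [A_J, D_J, ..., D_1] order with time-ascending blocks.
haar_matrix_oracle <- function(n = 32L) {
  J <- as.integer(log2(n))
  rows <- list(rep(1 / n, n))
  for (j in J:1) {
    block <- 2^j
    half <- 2^(j - 1)
    for (i in seq_len(n / block)) {
      r <- numeric(n)
      start <- (i - 1) * block
      r[(start + 1):(start + half)] <- 1 / block
      r[(start + half + 1):(start + block)] <- -1 / block
      rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, rows)
}

# Feature columns with exact empirical correlation structure: given a
# binary label vector and a loading matrix L (features in columns, rows =
# loadings on [label, noise basis 1, noise basis 2, ...]), returns columns
# f_k = sum_r L[r, k] * q_r where q_1 is the standardized label and the
# q_r are an exactly orthonormal centered basis.
exact_cor_features <- function(labels, loadings, seed = 1) {
  n <- length(labels)
  set.seed(seed)
  raw <- cbind(labels, matrix(rnorm(n * (nrow(loadings) - 1)), n))
  raw <- scale(raw, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(raw))
  q <- scale(q, center = FALSE, scale = apply(q, 2, sd))
  q %*% loadings
}
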