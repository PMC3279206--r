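# Fixture generators and independent oracles shared across the test files.
# Everything here is deliberately written by a different route than the
# package implementation it checks.

# --- sparse-recovery instances ---------------------------------------------

# Random unit-norm Gaussian dictionary with pairwise coherence below `mu_max`
# (atoms are rejection-sampled one at a time), plus a planted sparse
# coefficient vector with magnitudes in [0.5, 1.5].
random_sparse_instance <- function(seed, B = NULL, N = NULL, k = NULL,
                                   mu_max = 0.5) {
  set.seed(seed)
  if (is.null(B)) B <- sample(8:12, 1)
  if (is.null(N)) N <- sample(12:16, 1)
  if (is.null(k)) k <- sample(1:2, 1)
  A <- matrix(0, B, N)
  for (j in seq_len(N)) {
    for (try in 1:10000) {
      a <- rnorm(B)
      a <- a / sqrt(sum(a^2))
      if (j == 1 || max(abs(crossprod(A[, seq_len(j - 1), drop = FALSE], a))) < mu_max) {
        A[, j] <- a
        break
      }
      if (try == 10000) stop("could not sample a low-coherence atom")
    }
  }
  gamma <- numeric(N)
  supp <- sort(sample(N, k))
  gamma[supp] <- sample(c(-1, 1), k, replace = TRUE) * runif(k, 0.5, 1.5)
  list(A = A, gamma = gamma, support = supp, y = as.vector(A %*% gamma),
       B = B, N = N, k = k)
}

# --- ENVI byte-level oracle -------------------------------------------------

# Re-reads the raw binary with explicit per-interleave index arithmetic,
# independent of the package's array/aperm reshaping.
envi_byte_oracle <- function(header_path, H, W, B, interleave,
                             size = 8, what = "numeric", signed = TRUE) {
  data_path <- paste0(sub("\\.hdr$", "", header_path), ".raw")
  con <- file(data_path, "rb")
  on.exit(close(con))
  v <- readBin(con, what, n = H * W * B, size = size, signed = signed,
               endian = "little")
  out <- array(NA_real_, c(H, W, B))
  for (h in seq_len(H)) for (w in seq_len(W)) for (b in seq_len(B)) {
    idx <- switch(interleave,
      bsq = (b - 1) * H * W + (h - 1) * W + w,
      bil = (h - 1) * W * B + (b - 1) * W + w,
      bip = (h - 1) * W * B + (w - 1) * B + b)
    out[h, w, b] <- v[idx]
  }
  out
}

# --- brute-force 2-D median oracle -----------------------------------------

# Explicit per-pixel window gathering with clamped mirror indices and
# sort-and-take-middle, independent of the vectorized implementation.
median_oracle <- function(band, window) {
  r <- (window - 1) / 2
  H <- nrow(band); W <- ncol(band)
  refl <- function(i, n) {
    i <- ifelse(i < 1, 2 - i, i)
    i <- ifelse(i > n, 2 * n - i, i)
    pmin(pmax(i, 1), n)
  }
  out <- band
  for (i in seq_len(H)) for (j in seq_len(W)) {
    vals <- numeric(0)
    for (di in -r:r) for (dj in -r:r)
      vals <- c(vals, band[refl(i + di, H), refl(j + dj, W)])
    out[i, j] <- sort(vals)[(length(vals) + 1) / 2]
  }
  out
}

# --- hole-filling oracle ----------------------------------------------------

# Fixpoint dilation of the border-background region using whole-matrix
# shifts (no queue), then filling whatever background was never reached.
fill_holes_oracle <- function(mask, connectivity = 4) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- mask == 0
  reached <- matrix(FALSE, H, W)
  reached[c(1, H), ] <- bg[c(1, H), ]
  reached[, c(1, W)] <- bg[, c(1, W)]
  shift <- function(m, di, dj) {
    out <- matrix(FALSE, H, W)
    ri <- max(1, 1 + di):min(H, H + di)
    ci <- max(1, 1 + dj):min(W, W + dj)
    out[ri, ci] <- m[ri - di, ci - dj]
    out
  }
  deltas <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    deltas <- c(deltas, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  repeat {
    grown <- reached
    for (d in deltas) grown <- grown | shift(reached, d[1], d[2])
    grown <- grown & bg
    if (identical(grown, reached)) break
    reached <- grown
  }
  out <- mask
  out[bg & !reached] <- 1L
  out
}

# --- random blob masks ------------------------------------------------------

# Thresholded, box-smoothed Gaussian field: organic blobs with enclosed
# holes at many seeds.
random_blob_mask <- function(seed, H = 24, W = 24, smooth_iters = 2) {
  set.seed(seed)
  m <- matrix(rnorm(H * W), H, W)
  for (it in seq_len(smooth_iters)) {
    p <- m
    acc <- m
    cnt <- matrix(1, H, W)
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ri <- max(1, 1 + d[1]):min(H, H + d[1])
      ci <- max(1, 1 + d[2]):min(W, W + d[2])
      acc[ri, ci] <- acc[ri, ci] + p[ri - d[1], ci - d[2]]
      cnt[ri, ci] <- cnt[ri, ci] + 1
    }
    m <- acc / cnt
  }
  mask <- matrix(0L, H, W)
  mask[m > 0] <- 1L
  mask
}

# --- tiny scenes ------------------------------------------------------------

small_sim_config <- function(seed = 1, H = 24, W = 24, ...) {
  simulation_config(
    height = H, width = W, seed = seed,
    tumor_shapes = list(ellipse_shape(c(0.45 * H, 0.5 * W),
                                      c(0.2 * H, 0.25 * W), 20)),
    ...)
}
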