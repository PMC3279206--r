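#' Per-band 2-D median denoising
#'
#' Tongue scenes carry impulse-like noise from saliva glare and tongue
#' movement; a spatial median filter removes isolated speckle without
#' smearing tumor margins. Each band is filtered independently with a
#' `window x window` 2-D median; image borders are handled by mirror
#' (reflect) padding, so no dark-border artifact is introduced.
#'
#' @param cube a [spectral_cube()].
#' @param window odd integer >= 1; the default 3 is the smallest window that
#'   kills single-pixel speckle.
#' @return A [spectral_cube()] of the same shape, wavelengths and kind; each
#'   output value is one of the input values of the same band.
#' @examples
#' cube <- spectral_cube(array(1, c(5, 5, 81)), kind = "raw")
#' identical(median_denoise(cube, 3)$data, cube$data)
#' @export
median_denoise <- function(cube, window = 3L) {
  stopifnot(inherits(cube, "spectral_cube"))
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L || window %% 2L == 0L)
    stop_srhsi("`window` must be a positive odd integer", "srhsi_parameter_error")
  if (window == 1L) return(cube)
  d <- dim(cube$data)
  out <- cube$data
  r <- (window - 1L) %/% 2L
  ri <- .reflect_index(d[1], r)
  ci <- .reflect_index(d[2], r)
  mid <- (window^2 + 1L) %/% 2L
  for (b in seq_len(d[3])) {
    p <- cube$data[, , b][ri, ci]
    # stack the window^2 shifted copies as columns, then select the middle
    # order statistic with a vectorized odd-even transposition sort
    S <- matrix(0, d[1] * d[2], window^2)
    k <- 0L
    for (dj in 0:(window - 1L)) for (di in 0:(window - 1L)) {
      k <- k + 1L
      S[, k] <- as.vector(p[di + seq_len(d[1]), dj + seq_len(d[2])])
    }
    out[, , b] <- matrix(.row_kth(S, mid), d[1], d[2])
  }
  spectral_cube(out, cube$wavelengths_nm, cube$kind)
}

# mirror padding indices (numpy-style 'reflect': edge not repeated; degrades
# to edge replication when the dimension is shorter than the pad)
.reflect_index <- function(n, r) {
  idx <- c((r + 1L):2L, seq_len(n), (n - 1L):(n - r))[seq_len(n + 2L * r)]
  pmin(pmax(idx, 1L), n)
}

# k-th order statistic of each row, by full odd-even transposition sort over
# the columns (vectorized pmin/pmax passes; exact for any k)
.row_kth <- function(S, k) {
  m <- ncol(S)
  for (pass in seq_len(m)) {
    start <- if (pass %% 2L) 1L else 2L
    js <- seq(start, m - 1L, by = 2L)
    if (length(js) == 0L) next
    for (j in js) {
      lo <- pmin(S[, j], S[, j + 1L])
      S[, j + 1L] <- pmax(S[, j], S[, j + 1L])
      S[, j] <- lo
    }
  }
  S[, k]
}

#' Convert raw radiance to relative reflectance
#'
#' Calibrates a raw cube against a white-board reference and the camera's
#' dark current, per pixel and band:
#' \deqn{R(\lambda) = \frac{I_{raw}(\lambda) - I_{dark}(\lambda)}
#'                         {I_{white}(\lambda) - I_{dark}(\lambda)}}
#' The white board gives the incident-light estimate per wavelength; the dark
#' frame removes the sensor offset. Where the denominator magnitude falls
#' below `guard` (a dead band or dead pixel) the output is set to 0, and the
#' affected pixel/band indices are recorded in the
#' `"calibration_warnings"` attribute of the result (a data frame with
#' columns `row`, `col`, `band`) along with a `warning()`.
#'
#' @param raw a [spectral_cube()] with `kind == "raw"`.
#' @param refs a [reference_pair()] with shapes matching `raw`.
#' @param guard small positive denominator threshold (default `1e-9`).
#' @return A reflectance [spectral_cube()]. Values are unbounded above
#'   (glare pixels exceed 1).
#' @export
normalize_reflectance <- function(raw, refs, guard = 1e-9) {
  stopifnot(inherits(raw, "spectral_cube"), inherits(refs, "reference_pair"))
  if (raw$kind != "raw")
    stop_srhsi("`raw` must be a raw-radiance cube", "srhsi_consistency_error")
  if (!identical(dim(raw$data), dim(refs$white)))
    stop_srhsi("reference frames do not match the cube's shape",
               "srhsi_consistency_error")
  denom <- refs$white - refs$dark
  bad <- abs(denom) < guard
  R <- (raw$data - refs$dark) / denom
  R[bad] <- 0
  out <- spectral_cube(R, raw$wavelengths_nm, kind = "reflectance")
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    attr(out, "calibration_warnings") <-
      data.frame(row = idx[, 1], col = idx[, 2], band = idx[, 3])
    warning(sprintf("calibration: %d pixel/band value(s) had |white - dark| < %g; set to 0",
                    sum(bad), guard), call. = FALSE)
  } else {
    attr(out, "calibration_warnings") <-
      data.frame(row = integer(0), col = integer(0), band = integer(0))
  }
  out
}
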