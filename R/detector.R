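#' @noRd
new_spectral_dictionary <- function(atoms, labels, wavelengths_nm = NULL,
                                    normalized = NULL) {
  if (!is.matrix(atoms) || ncol(atoms) != length(labels))
    stop_srhsi("atoms must be a B x N matrix with one label per column",
               "srhsi_consistency_error")
  labels <- as.character(labels)
  if (!all(labels %in% c("noncancerous", "cancerous")))
    stop_srhsi("atom labels must be 'noncancerous' or 'cancerous'",
               "srhsi_format_error")
  n_nc <- sum(labels == "noncancerous")
  n_c <- sum(labels == "cancerous")
  if (n_nc < 1L || n_c < 1L)
    stop_srhsi("dictionary needs at least one atom of each class",
               "srhsi_configuration_error")
  # the concatenated dictionary is [A_nc A_c]: noncancerous block first
  if (!identical(labels, c(rep("noncancerous", n_nc), rep("cancerous", n_c))))
    stop_srhsi("atoms must form two contiguous class blocks, noncancerous first",
               "srhsi_consistency_error")
  if (is.null(normalized)) {
    cn <- sqrt(colSums(atoms^2))
    normalized <- all(abs(cn - 1) <= 1e-10)
  }
  structure(list(atoms = atoms, labels = labels,
                 n_noncancerous = n_nc, n_cancerous = n_c,
                 normalized = normalized, wavelengths_nm = wavelengths_nm),
            class = "spectral_dictionary")
}

#' @export
print.spectral_dictionary <- function(x, ...) {
  cat(sprintf("<spectral_dictionary> %d bands, %d + %d atoms (noncancerous + cancerous), %s\n",
              nrow(x$atoms), x$n_noncancerous, x$n_cancerous,
              if (x$normalized) "unit-norm columns" else "unnormalized"))
  invisible(x)
}

#' Build the two-class spectral dictionary
#'
#' Stacks training spectra of the two tissue classes into the concatenated
#' dictionary `A = [A_nc  A_c]` (noncancerous block first), one atom per
#' column. A test spectrum of either class approximately lies in the
#' low-dimensional subspace spanned by the training spectra of its own
#' class, which is what the residual comparison in [classify_pixel()]
#' exploits. Columns are scaled to unit l2 norm by default so that atom
#' selection is not biased toward bright spectra.
#'
#' @param normal_spectra `N_nc x B` matrix, one noncancerous training
#'   spectrum per row.
#' @param cancer_spectra `N_c x B` matrix of cancerous training spectra.
#' @param normalize scale every atom to unit l2 norm (default `TRUE`).
#' @param wavelengths_nm optional wavelength grid carried for provenance.
#' @return A `spectral_dictionary`.
#' @export
build_dictionary <- function(normal_spectra, cancer_spectra, normalize = TRUE,
                             wavelengths_nm = NULL) {
  normal_spectra <- rbind(normal_spectra)
  cancer_spectra <- rbind(cancer_spectra)
  if (nrow(normal_spectra) < 1L || nrow(cancer_spectra) < 1L)
    stop_srhsi("both classes need at least one training spectrum",
               "srhsi_configuration_error")
  if (ncol(normal_spectra) != ncol(cancer_spectra))
    stop_srhsi("training spectra of the two classes differ in band count",
               "srhsi_consistency_error")
  atoms <- t(rbind(normal_spectra, cancer_spectra))
  if (normalize) {
    cn <- sqrt(colSums(atoms^2))
    if (any(cn < 1e-12))
      stop_srhsi("cannot normalize an all-zero training spectrum",
                 "srhsi_degenerate_atom_error")
    atoms <- sweep(atoms, 2, cn, "/")
  }
  labels <- c(rep("noncancerous", nrow(normal_spectra)),
              rep("cancerous", nrow(cancer_spectra)))
  new_spectral_dictionary(atoms, labels, wavelengths_nm, normalized = normalize)
}

#' Classify one pixel spectrum by sparse-representation residuals
#'
#' Recovers a sparse coefficient vector `gamma` for the spectrum over the
#' concatenated dictionary, splits it into the noncancerous block
#' (`alpha`) and cancerous block (`beta`), and compares the class-wise
#' reconstruction residuals
#' `r_nc = ||x - A_nc alpha||_2` and `r_c = ||x - A_c beta||_2`
#' through the decision score
#' \deqn{D(x) = \log_{10}\frac{r_{nc}(x)}{r_c(x)}.}
#' `D(x) > 0` (the own-class cancerous reconstruction is better) labels the
#' pixel cancerous; `D(x) <= 0` labels it noncancerous. Residuals are
#' floored at `floor` before the ratio so that exact reconstructions cannot
#' produce a non-finite score.
#'
#' @param x length-B spectrum (finite).
#' @param dict a [build_dictionary()] result with matching band count.
#' @param cfg a [solver_config()].
#' @param floor residual floor, default `1e-12`.
#' @return A `sparse_code` object with fields `gamma` (the
#'   `sparse_coefficients` over the full dictionary), `r_nc`, `r_c`,
#'   `score` and `label`.
#' @export
classify_pixel <- function(x, dict, cfg = solver_config(), floor = 1e-12) {
  stopifnot(inherits(dict, "spectral_dictionary"))
  if (length(x) != nrow(dict$atoms))
    stop_srhsi("spectrum length does not match the dictionary band count",
               "srhsi_consistency_error")
  if (any(!is.finite(x)))
    stop_srhsi("spectrum must be finite", "srhsi_consistency_error")
  gamma <- .sparse_fit(x, dict$atoms, cfg)
  sc <- .score_from_gamma(x, gamma$values, dict, floor)
  structure(c(list(gamma = gamma), sc), class = "sparse_code")
}

.score_from_gamma <- function(x, values, dict, floor) {
  nc_idx <- seq_len(dict$n_noncancerous)
  alpha <- values[nc_idx]
  beta <- values[-nc_idx]
  r_nc <- l2norm(x - as.vector(dict$atoms[, nc_idx, drop = FALSE] %*% alpha))
  r_c <- l2norm(x - as.vector(dict$atoms[, -nc_idx, drop = FALSE] %*% beta))
  score <- log10(max(r_nc, floor) / max(r_c, floor))
  list(r_nc = r_nc, r_c = r_c, score = score,
       label = if (score > 0) "cancerous" else "noncancerous")
}

#' @export
print.sparse_code <- function(x, ...) {
  cat(sprintf("<sparse_code> r_nc = %.4g, r_c = %.4g, D = %+.4f -> %s\n",
              x$r_nc, x$r_c, x$score, x$label))
  invisible(x)
}

#' Classify every pixel of a reflectance cube
#'
#' Applies [classify_pixel()] to each pixel spectrum and assembles the
#' per-pixel decision scores and the raw binary detection mask
#' (`raw_mask == (scores > 0)`). The final mask equals the raw mask until
#' [fill_holes()] is applied.
#'
#' @param cube a reflectance [spectral_cube()] whose band count matches the
#'   dictionary.
#' @param dict a `spectral_dictionary`.
#' @param cfg a [solver_config()].
#' @param mask_of_interest optional [label_mask()]; pixels marked 255 in it
#'   are skipped (score `NA`, mask 0). All other pixels are classified
#'   regardless of their annotation.
#' @param floor residual floor passed to the decision rule.
#' @return A `detection_map` with `scores` (H x W, `NA` at skipped pixels),
#'   `raw_mask` and `final_mask` (H x W 0/1 integer matrices).
#' @export
classify_cube <- function(cube, dict, cfg = solver_config(),
                          mask_of_interest = NULL, floor = 1e-12) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(dict, "spectral_dictionary"))
  if (cube$kind != "reflectance")
    stop_srhsi("classification expects a reflectance cube", "srhsi_consistency_error")
  d <- dim(cube$data)
  if (d[3] != nrow(dict$atoms))
    stop_srhsi(sprintf("cube has %d bands but the dictionary has %d",
                       d[3], nrow(dict$atoms)), "srhsi_consistency_error")
  npix <- d[1] * d[2]
  X <- matrix(cube$data, npix, d[3])  # rows are pixel spectra
  todo <- rep(TRUE, npix)
  if (!is.null(mask_of_interest)) {
    stopifnot(inherits(mask_of_interest, "label_mask"))
    if (!identical(dim(mask_of_interest$labels), d[1:2]))
      stop_srhsi("mask of interest does not match the cube's spatial shape",
                 "srhsi_consistency_error")
    todo <- as.vector(mask_of_interest$labels != 255L)
  }
  scores <- rep(NA_real_, npix)
  A <- dict$atoms
  for (p in which(todo)) {
    x <- X[p, ]
    fit <- tryCatch(.sparse_fit(x, A, cfg), error = function(e) {
      ij <- arrayInd(p, d[1:2])
      stop_srhsi(sprintf("solver failed at pixel (%d, %d): %s",
                         ij[1], ij[2], conditionMessage(e)), "srhsi_solver_error")
    })
    scores[p] <- .score_from_gamma(x, fit$values, dict, floor)$score
  }
  scores <- matrix(scores, d[1], d[2])
  raw_mask <- matrix(0L, d[1], d[2])
  raw_mask[!is.na(scores) & scores > 0] <- 1L
  structure(list(scores = scores, raw_mask = raw_mask, final_mask = raw_mask),
            class = "detection_map")
}

#' @export
print.detection_map <- function(x, ...) {
  cat(sprintf("<detection_map> %d x %d, %d raw detections, %d after post-processing\n",
              nrow(x$scores), ncol(x$scores), sum(x$raw_mask), sum(x$final_mask)))
  invisible(x)
}

#' Fill enclosed holes in the detection mask
#'
#' Glare (specular reflection off saliva) destroys the spectra of isolated
#' interior pixels, which then fail to be detected and leave holes inside
#' the tumor region. Morphological hole filling closes them: every
#' background connected component that is *not* connected to the image
#' border is set to foreground. Foreground pixels are never removed.
#'
#' @param map a `detection_map` from [classify_cube()], or a 0/1 matrix.
#' @param connectivity background connectivity, 4 (default) or 8. The usual
#'   duality pairs 8-connected foreground with 4-connected background.
#' @return The `detection_map` with `final_mask` updated (or, for a matrix
#'   input, the filled 0/1 matrix).
#' @export
fill_holes <- function(map, connectivity = c(4, 8)) {
  connectivity <- as.integer(match.arg(as.character(connectivity[1]), c("4", "8")))
  m <- if (inherits(map, "detection_map")) map$raw_mask else map
  filled <- .fill_holes_mask(m, connectivity)
  if (inherits(map, "detection_map")) {
    map$final_mask <- filled
    map
  } else filled
}

# flood the background from the border (breadth-first over a preallocated
# queue); unreached background pixels are enclosed holes
.fill_holes_mask <- function(mask, connectivity) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- mask == 0L
  reached <- matrix(FALSE, H, W)
  seeds <- which(bg & (row(mask) == 1L | row(mask) == H |
                       col(mask) == 1L | col(mask) == W))
  if (length(seeds) == 0L) {
    out <- mask
    out[bg] <- 1L
    return(out)
  }
  queue <- integer(H * W)
  queue[seq_along(seeds)] <- seeds
  head <- 1L; tail <- length(seeds)
  reached[seeds] <- TRUE
  drow <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)[seq_len(connectivity)]
  dcol <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)[seq_len(connectivity)]
  while (head <= tail) {
    p <- queue[head]; head <- head + 1L
    pr <- ((p - 1L) %% H) + 1L
    pc <- ((p - 1L) %/% H) + 1L
    for (k in seq_len(connectivity)) {
      nr <- pr + drow[k]; nc <- pc + dcol[k]
      if (nr < 1L || nr > H || nc < 1L || nc > W) next
      q <- nr + (nc - 1L) * H
      if (bg[q] && !reached[q]) {
        reached[q] <- TRUE
        tail <- tail + 1L
        queue[tail] <- q
      }
    }
  }
  out <- mask
  out[bg & !reached] <- 1L
  out
}
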