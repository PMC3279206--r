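#' Default two-class reflectance signatures
#'
#' Smooth synthetic stand-ins for the mean reflectance spectra of normal and
#' tumor tongue tissue and their per-wavelength standard deviations. The
#' normal-tissue mean is a logistic rise across the red/near-infrared edge
#' plus a gentle slope; the tumor mean adds a smooth near-infrared bump whose
#' supremum-norm height equals `separation` exactly on the grid. The sd
#' profiles are positive and grow toward 1000 nm (about 0.02 to 0.05), where
#' sensor response drops; the tumor class is slightly noisier. These shapes
#' are explicitly synthetic defaults chosen for class-separability structure,
#' not measured tissue data.
#'
#' @param B number of bands (>= 2); the grid is `seq(600, 1000, length.out = B)`.
#' @param separation supremum-norm distance between the two class means, in
#'   reflectance units, in `[0, 1]`.
#' @return A list with `mean_normal`, `mean_cancer`, `sd_normal`,
#'   `sd_cancer` (each length B) and the `wavelengths_nm` grid.
#' @examples
#' sig <- default_signatures(81, 0.15)
#' max(abs(sig$mean_cancer - sig$mean_normal))
#' @export
default_signatures <- function(B, separation = 0.15) {
  B <- as.integer(B)
  if (B < 2L) stop_srhsi("B must be at least 2", "srhsi_parameter_error")
  if (separation < 0 || separation > 1)
    stop_srhsi("`separation` must lie in [0, 1]", "srhsi_parameter_error")
  lambda <- seq(600, 1000, length.out = B)
  t <- (lambda - 600) / 400
  mean_normal <- 0.22 + 0.18 / (1 + exp(-(lambda - 760) / 45)) + 0.05 * t
  bump <- exp(-((lambda - 800) / 110)^2)
  bump <- bump / max(bump)  # sup norm of the class difference == separation
  mean_cancer <- mean_normal + separation * bump
  sd_normal <- 0.02 + 0.03 * t
  list(mean_normal = mean_normal, mean_cancer = mean_cancer,
       sd_normal = sd_normal, sd_cancer = 1.15 * sd_normal,
       wavelengths_nm = lambda)
}

#' Elliptical tumor region
#'
#' @param center length-2 numeric, (row, col) center in pixels.
#' @param axes length-2 numeric, semi-axes in pixels.
#' @param angle_deg rotation of the first axis, counter-clockwise degrees.
#' @return A list describing the ellipse, for `tumor_shapes`.
#' @export
ellipse_shape <- function(center, axes, angle_deg = 0) {
  stopifnot(length(center) == 2L, length(axes) == 2L, all(axes > 0))
  list(center = as.numeric(center), axes = as.numeric(axes),
       angle_deg = as.numeric(angle_deg))
}

#' Simulation configuration
#'
#' Describes a synthetic tongue scene: scene geometry, the two class
#' signatures, tumor ellipses, saliva-glare impulse noise, and the
#' illumination/dark-current model used to turn true reflectance into raw
#' radiance counts (the inverse of the calibration in
#' [normalize_reflectance()]). The defaults are the package's reference
#' study conditions: a 64 x 64 scene over the 81-band 600--1000 nm grid,
#' class means separated by 0.15 in supremum norm, constant per-band noise
#' sd 0.03 for both classes, one elliptical tumor covering roughly 11% of
#' the frame, 1% glare pixels saturating at reflectance 1.5, a smooth lamp
#' spectrum of a few thousand counts and a dark level of 100 counts with
#' 0.5-count read noise.
#'
#' @param height,width scene size in pixels.
#' @param wavelengths_nm strictly increasing band grid.
#' @param mean_normal,mean_cancer length-B class mean reflectance profiles
#'   in (0, 1); default from [default_signatures()] at `separation`.
#' @param sd_normal,sd_cancer length-B per-band noise sd; default constant
#'   0.03.
#' @param separation supremum-norm class separation used when the means are
#'   left `NULL`.
#' @param tumor_shapes list of [ellipse_shape()] regions rasterized to class 1.
#' @param glare_fraction per-pixel probability of a saliva-glare impulse.
#' @param impulse_value reflectance written into glare pixels (above white).
#' @param illumination_gain length-B positive lamp spectrum, in counts.
#' @param dark_level mean dark-current level, counts.
#' @param dark_read_sd sd of the Gaussian read noise on the dark frame.
#' @param seed integer RNG seed; identical seeds give bit-identical scenes.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(height = 64L, width = 64L,
                              wavelengths_nm = seq(600, 1000, by = 5),
                              mean_normal = NULL, mean_cancer = NULL,
                              sd_normal = NULL, sd_cancer = NULL,
                              separation = 0.15,
                              tumor_shapes = list(
                                ellipse_shape(c(0.42, 0.55) * c(height, width),
                                              c(0.16 * height, 0.23 * width),
                                              angle_deg = 25)),
                              glare_fraction = 0.01,
                              impulse_value = 1.5,
                              illumination_gain = NULL,
                              dark_level = 100,
                              dark_read_sd = 0.5,
                              seed = 1L) {
  B <- length(wavelengths_nm)
  if (B < 2L || any(diff(wavelengths_nm) <= 0))
    stop_srhsi("wavelengths must be strictly increasing, length >= 2",
               "srhsi_parameter_error")
  if (is.null(mean_normal) || is.null(mean_cancer)) {
    sig <- default_signatures(B, separation)
    if (is.null(mean_normal)) mean_normal <- sig$mean_normal
    if (is.null(mean_cancer)) mean_cancer <- sig$mean_cancer
  }
  if (is.null(sd_normal)) sd_normal <- rep(0.03, B)
  if (is.null(sd_cancer)) sd_cancer <- rep(0.03, B)
  if (is.null(illumination_gain))
    illumination_gain <- 3000 * (0.6 + 0.8 * exp(-((wavelengths_nm - 820) / 180)^2))
  for (nm in c("mean_normal", "mean_cancer", "sd_normal", "sd_cancer",
               "illumination_gain")) {
    v <- get(nm)
    if (length(v) != B)
      stop_srhsi(sprintf("`%s` must have one value per band (%d)", nm, B),
                 "srhsi_parameter_error")
  }
  if (any(mean_normal <= 0 | mean_normal >= 1 | mean_cancer <= 0 | mean_cancer >= 1))
    stop_srhsi("class mean profiles must lie in (0, 1)", "srhsi_parameter_error")
  if (any(sd_normal < 0) || any(sd_cancer < 0))
    stop_srhsi("sd profiles must be non-negative", "srhsi_parameter_error")
  if (glare_fraction < 0 || glare_fraction >= 1)
    stop_srhsi("`glare_fraction` must lie in [0, 1)", "srhsi_parameter_error")
  if (any(illumination_gain <= 0))
    stop_srhsi("`illumination_gain` must be positive", "srhsi_parameter_error")
  structure(list(
    height = as.integer(height), width = as.integer(width),
    wavelengths_nm = as.numeric(wavelengths_nm),
    mean_normal = mean_normal, mean_cancer = mean_cancer,
    sd_normal = sd_normal, sd_cancer = sd_cancer,
    tumor_shapes = tumor_shapes,
    glare_fraction = glare_fraction, impulse_value = impulse_value,
    illumination_gain = illumination_gain,
    dark_level = dark_level, dark_read_sd = dark_read_sd,
    seed = as.integer(seed)), class = "simulation_config")
}

.rasterize_ellipses <- function(shapes, H, W) {
  truth <- matrix(0L, H, W)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (sh in shapes) {
    th <- sh$angle_deg * pi / 180
    dr <- rr - sh$center[1]
    dc <- cc - sh$center[2]
    u <- cos(th) * dr + sin(th) * dc
    v <- -sin(th) * dr + cos(th) * dc
    inside <- (u / sh$axes[1])^2 + (v / sh$axes[2])^2 <= 1
    if (!any(inside))
      warning("a tumor ellipse lies fully outside the frame", call. = FALSE)
    truth[inside] <- 1L
  }
  truth
}

#' Simulate a raw scene with references and ground truth
#'
#' Builds a complete synthetic acquisition: a ground-truth tumor mask from
#' rasterized ellipses; a true-reflectance cube (class mean plus independent
#' per-band Gaussian noise with the class sd, clamped at 0); saliva glare as
#' Bernoulli-selected pixels whose reflectance is set to `impulse_value`
#' across a random contiguous band range; and the raw radiance cube
#' `raw = R * (white - dark) + dark` -- the exact inverse of the
#' white/dark calibration -- with `white` the lamp spectrum broadcast over
#' the scene and `dark` the dark level plus Gaussian read noise. With zero
#' noise and glare, [normalize_reflectance()] applied to `raw` and `refs`
#' recovers `true_reflectance` to floating-point accuracy.
#'
#' @param cfg a [simulation_config()].
#' @return A `simulated_scene`: `raw` (raw [spectral_cube()]), `refs`
#'   ([reference_pair()]), `truth` ([label_mask()]) and `true_reflectance`
#'   (reflectance [spectral_cube()]).
#' @export
simulate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  H <- cfg$height; W <- cfg$width
  B <- length(cfg$wavelengths_nm)
  withr::with_seed(cfg$seed, {
    truth <- .rasterize_ellipses(cfg$tumor_shapes, H, W)
    tum <- truth == 1L
    R <- array(0, c(H, W, B))
    for (b in seq_len(B)) {
      m <- ifelse(tum, cfg$mean_cancer[b], cfg$mean_normal[b])
      s <- ifelse(tum, cfg$sd_cancer[b], cfg$sd_normal[b])
      R[, , b] <- m + stats::rnorm(H * W) * s
    }
    R[R < 0] <- 0
    if (cfg$glare_fraction > 0) {
      glare <- which(stats::runif(H * W) < cfg$glare_fraction)
      for (p in glare) {
        b1 <- sample.int(B, 1L)
        b2 <- sample.int(B, 1L)
        ij <- arrayInd(p, c(H, W))
        R[ij[1], ij[2], min(b1, b2):max(b1, b2)] <- cfg$impulse_value
      }
    }
    white <- array(rep(cfg$illumination_gain, each = H * W), c(H, W, B))
    dark <- array(cfg$dark_level + stats::rnorm(H * W * B, 0, cfg$dark_read_sd),
                  c(H, W, B))
    raw <- R * (white - dark) + dark
  })
  structure(list(
    raw = spectral_cube(raw, cfg$wavelengths_nm, kind = "raw"),
    refs = reference_pair(white, dark),
    truth = label_mask(truth),
    true_reflectance = spectral_cube(R, cfg$wavelengths_nm, kind = "reflectance")
  ), class = "simulated_scene")
}

#' Per-class random train/test split of labeled pixels
#'
#' Mirrors the clinical protocol of training on a small random fraction of
#' the annotated pixels (around 10%) and testing on the rest. The split is
#' drawn independently per class, without replacement; train size is
#' `round(train_frac * class size)`, at least 1 and at most size - 1.
#' Unlabeled (255) pixels never enter either side.
#'
#' @param truth a [label_mask()].
#' @param train_frac fraction in (0, 1); default 0.1.
#' @param seed integer RNG seed.
#' @return A list `train` / `test`, each holding `noncancerous` and
#'   `cancerous` integer vectors of linear (column-major) pixel indices.
#' @export
split_train_test <- function(truth, train_frac = 0.1, seed = 1L) {
  stopifnot(inherits(truth, "label_mask"))
  if (train_frac <= 0 || train_frac >= 1)
    stop_srhsi("`train_frac` must lie strictly between 0 and 1",
               "srhsi_parameter_error")
  idx <- list(noncancerous = which(truth$labels == 0L),
              cancerous = which(truth$labels == 1L))
  for (cl in names(idx))
    if (length(idx[[cl]]) < 2L)
      stop_srhsi(sprintf("class '%s' has fewer than 2 labeled pixels", cl),
                 "srhsi_split_error")
  withr::with_seed(as.integer(seed), {
    train <- lapply(idx, function(ii) {
      n_tr <- max(1L, min(length(ii) - 1L, round(train_frac * length(ii))))
      sort(sample(ii, n_tr))
    })
  })
  test <- Map(setdiff, idx, train)
  list(train = train, test = test)
}

# pixel spectra at linear indices, as an n x B matrix
.pixel_spectra <- function(cube, indices) {
  d <- dim(cube$data)
  X <- matrix(cube$data, d[1] * d[2], d[3])
  X[indices, , drop = FALSE]
}
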