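#' Confusion counts and FPR/FNR/accuracy over labeled pixels
#'
#' Scores a binary prediction against ground truth using the pixel-level
#' rate definitions standard in tumor detection: the false negative rate is
#' the number of false-negative pixels over the total number of tumor
#' pixels, the false positive rate is the number of false-positive pixels
#' over the total number of normal-tissue pixels, and accuracy is the
#' fraction of correctly classified labeled pixels. Unlabeled truth pixels
#' (255) are excluded from every count. Rates are percentages; a rate whose
#' denominator is zero is reported as `NA` (not applicable).
#'
#' @param pred a `detection_map` (its `final_mask` is used), a
#'   [label_mask()], or a 0/1 matrix. Predictions must be 0/1 at every
#'   labeled truth pixel.
#' @param truth a [label_mask()] of the same spatial shape.
#' @return An `eval_report`: integer counts `tp`, `fp`, `tn`, `fn` and
#'   percentage rates `fpr`, `fnr`, `accuracy`.
#' @examples
#' p <- label_mask(matrix(c(1L, 0L, 0L, 0L), 2, 2))
#' t <- label_mask(matrix(c(1L, 0L, 1L, 0L), 2, 2))
#' confusion(p, t)
#' @export
confusion <- function(pred, truth) {
  stopifnot(inherits(truth, "label_mask"))
  pm <- if (inherits(pred, "detection_map")) pred$final_mask
        else if (inherits(pred, "label_mask")) pred$labels
        else pred
  if (!is.matrix(pm) || !identical(dim(pm), dim(truth$labels)))
    stop_srhsi("prediction and truth shapes differ", "srhsi_consistency_error")
  labeled <- truth$labels != 255L
  if (!any(labeled))
    stop_srhsi("truth mask has no labeled pixels", "srhsi_evaluation_error")
  p <- pm[labeled]
  t <- truth$labels[labeled]
  if (!all(p %in% c(0L, 1L)))
    stop_srhsi("predictions must be 0/1 at labeled pixels", "srhsi_format_error")
  tp <- sum(p == 1L & t == 1L)
  fp <- sum(p == 1L & t == 0L)
  tn <- sum(p == 0L & t == 0L)
  fn <- sum(p == 0L & t == 1L)
  new_eval_report(tp, fp, tn, fn)
}

new_eval_report <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  structure(list(
    tp = as.integer(tp), fp = as.integer(fp),
    tn = as.integer(tn), fn = as.integer(fn),
    fnr = if (tp + fn > 0) 100 * fn / (tp + fn) else NA_real_,
    fpr = if (fp + tn > 0) 100 * fp / (fp + tn) else NA_real_,
    accuracy = 100 * (tp + tn) / total
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> tp %d  fp %d  tn %d  fn %d | FPR %s%%  FNR %s%%  accuracy %.2f%%\n",
              x$tp, x$fp, x$tn, x$fn,
              if (is.na(x$fpr)) "NA" else sprintf("%.2f", x$fpr),
              if (is.na(x$fnr)) "NA" else sprintf("%.2f", x$fnr),
              x$accuracy))
  invisible(x)
}

#' Pipeline configuration
#'
#' @param median_window odd window of the spatial median filter.
#' @param guard calibration division guard.
#' @param solver a [solver_config()].
#' @param train_frac labeled-pixel fraction used for the dictionary.
#' @param fill connectivity-aware hole filling of the raw detection mask.
#' @param connectivity background connectivity for [fill_holes()].
#' @param seed RNG seed for the train/test split.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(median_window = 3L, guard = 1e-9,
                            solver = solver_config("greedy"),
                            train_frac = 0.1, fill = TRUE,
                            connectivity = 4L, seed = 1L) {
  structure(list(median_window = as.integer(median_window), guard = guard,
                 solver = solver, train_frac = train_frac, fill = isTRUE(fill),
                 connectivity = as.integer(connectivity), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full detection pipeline on a scene
#'
#' Orchestrates the end-to-end chain: simulate (or accept) a scene, median
#' denoise the raw cube, calibrate to reflectance, split the labeled pixels
#' per class into train and test, build the two-class dictionary from the
#' training spectra, classify every pixel, fill holes in the detection
#' mask, and score the result. Two reports are produced: `report` over the
#' held-out test pixels (the headline number) and `report_all` over all
#' labeled pixels. The run manifest records the seed, a configuration hash
#' and version strings; identical inputs give byte-identical manifests and
#' reports.
#'
#' @param scene a [simulation_config()] (the scene is simulated here) or a
#'   `simulated_scene` from [simulate_scene()].
#' @param pipe a [pipeline_config()].
#' @return A list with `map` (`detection_map`), `report` and `report_all`
#'   (`eval_report`s), `split`, `dictionary` and `manifest`.
#' @export
run_pipeline <- function(scene, pipe = pipeline_config()) {
  stopifnot(inherits(pipe, "pipeline_config"))
  sim_cfg <- NULL
  if (inherits(scene, "simulation_config")) {
    sim_cfg <- scene
    scene <- .stage("simulate", simulate_scene(sim_cfg))
  }
  if (!inherits(scene, "simulated_scene"))
    stop_srhsi("`scene` must be a simulation_config or simulated_scene",
               "srhsi_parameter_error")
  den <- .stage("median_denoise", median_denoise(scene$raw, pipe$median_window))
  refl <- .stage("normalize_reflectance",
                 suppressWarnings(normalize_reflectance(den, scene$refs, pipe$guard)))
  split <- .stage("split_train_test",
                  split_train_test(scene$truth, pipe$train_frac, pipe$seed))
  dict <- .stage("build_dictionary", build_dictionary(
    .pixel_spectra(refl, split$train$noncancerous),
    .pixel_spectra(refl, split$train$cancerous),
    wavelengths_nm = refl$wavelengths_nm))
  map <- .stage("classify_cube", classify_cube(refl, dict, pipe$solver))
  if (pipe$fill) map <- .stage("fill_holes", fill_holes(map, pipe$connectivity))
  truth_test <- scene$truth$labels
  truth_test[] <- 255L
  test_idx <- c(split$test$noncancerous, split$test$cancerous)
  truth_test[test_idx] <- scene$truth$labels[test_idx]
  report <- .stage("confusion", confusion(map, label_mask(truth_test)))
  report_all <- confusion(map, scene$truth)
  manifest <- list(
    seed = pipe$seed,
    config_hash = rlang::hash(list(sim = sim_cfg, pipe = pipe)),
    pipeline = list(median_window = pipe$median_window,
                    solver = pipe$solver$method,
                    train_frac = pipe$train_frac,
                    fill = pipe$fill, connectivity = pipe$connectivity),
    versions = list(srhsi = as.character(utils::packageVersion("srhsi")),
                    r = paste(R.version$major, R.version$minor, sep = "."))
  )
  list(map = map, report = report, report_all = report_all,
       split = split, dictionary = dict, manifest = manifest)
}

# attach the stage name to any propagated error
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_srhsi(sprintf("[stage %s] %s", name, conditionMessage(e)),
               "srhsi_stage_error")
  })
}
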