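#' Run the full body-composition pipeline on one CT volume
#'
#' Segments every slice with a trained network, quantifies the L3 area and
#' the L3 +/- 20-slice volume of each tissue, computes the SMI and the
#' sarcopenia classification, and (optionally) writes all artifacts plus a
#' run manifest.
#'
#' @param volume a [ct_volume()] or path to a NIfTI file.
#' @param fit a trained `seg_fit` or path to a checkpoint.
#' @param l3_index 1-based index of the L3 slice (required; no automatic
#'   vertebra detection is performed).
#' @param height patient height in m.
#' @param cutoff SMI cutoff, cm²/m² (default female, 38.5).
#' @param sex used only to pick the default cutoff when `cutoff` is missing.
#' @param out_dir optional output directory for masks, CSV and manifest.
#' @param seed integer seed recorded in the manifest.
#' @param half slices on each side of L3 in the volume window (default 20,
#'   i.e. the standard 41-slice window).
#' @return list of class `pipeline_result`: `l3_areas` (cm²),
#'   `volumes` (cm³ over the 41-slice window), `smi`, `sarcopenia`
#'   (logical), `cutoff`, `masks`, and `manifest`.
#' @export
run_full_pipeline <- function(volume, fit, l3_index, height,
                              cutoff = NULL, sex = "female",
                              out_dir = NULL, seed = 1L, half = 20L) {
  t0 <- Sys.time()
  if (missing(l3_index) || is.null(l3_index))
    stop("l3_index is required: supply the L3 slice index (no auto-detection)")
  if (is.character(volume)) volume <- read_ct_volume(volume)
  if (is.character(fit)) fit <- load_checkpoint(fit)
  if (is.null(cutoff)) cutoff <- smi_cutoff(sex)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  win <- stage("l3_window", l3_window(volume, l3_index, half = half))
  masks <- stage("segment", predict(fit, win))
  q <- stage("quantify",
             quantify_masks(masks, pixel_spacing = volume$pixel_spacing,
                            slice_thickness = volume$slice_thickness))
  center <- (n_slices(win) + 1L) %/% 2L
  l3_areas <- q$areas[center, ]
  smi <- stage("smi", compute_smi(l3_areas[["muscle"]], height))
  result <- structure(list(
    l3_areas = l3_areas, volumes = q$volumes, areas = q$areas,
    smi = smi, sarcopenia = classify_sarcopenia(smi, cutoff),
    cutoff = cutoff, masks = masks,
    manifest = list(
      package_version = as.character(utils::packageVersion("bodycomp")),
      seed = seed, l3_index = l3_index, height = height, cutoff = cutoff,
      variant = fit$network$config$variant,
      pixel_spacing = volume$pixel_spacing,
      slice_thickness = volume$slice_thickness,
      n_slices = n_slices(volume),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_masks(masks, file.path(out_dir, "masks.nii.gz"))
    df <- data.frame(tissue = colnames(q$areas),
                     area_l3_cm2 = as.numeric(l3_areas),
                     volume_cm3 = as.numeric(q$volumes))
    write.csv(df, file.path(out_dir, "quantification.csv"), row.names = FALSE)
    man <- result$manifest
    man$output_checksums <- vapply(
      c("masks.nii.gz", "quantification.csv"),
      function(f) unname(tools::md5sum(file.path(out_dir, f))), "")
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    result$manifest <- man
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Body-composition pipeline result\n")
  cat(sprintf("  L3 areas (cm²): subq %.1f, visceral %.1f, muscle %.1f\n",
              x$l3_areas[["subq"]], x$l3_areas[["visceral"]],
              x$l3_areas[["muscle"]]))
  cat(sprintf("  41-slice volumes (cm³): subq %.1f, visceral %.1f, muscle %.1f\n",
              x$volumes[["subq"]], x$volumes[["visceral"]],
              x$volumes[["muscle"]]))
  cat(sprintf("  SMI %.2f cm²/m² -> %s (cutoff %.4g)\n", x$smi,
              if (x$sarcopenia) "sarcopenia" else "non-sarcopenia", x$cutoff))
  invisible(x)
}

#' Screen a cohort with the Auto SMI model
#'
#' Computes SMI from (possibly noisy) measured muscle areas, classifies at
#' the given cutoff, compares with gold labels, and derives the ROC curve,
#' AUC and Youden-optimal cutoff.
#'
#' @param cohort data frame with columns height_m and label, plus
#'   muscle_area_cm2.
#' @param measured_areas optional vector of automatically measured L3 muscle
#'   areas, cm² (defaults to the cohort's `muscle_area_cm2`).
#' @param cutoff SMI classification cutoff (default female, 38.5).
#' @return list of class `screening_result`: `report`
#'   (a [screening_stats()] object), `roc`, `auc`, `youden`, `smi`.
#' @export
screen_cohort <- function(cohort, measured_areas = NULL,
                          cutoff = smi_cutoff("female")) {
  if (is.null(measured_areas)) measured_areas <- cohort$muscle_area_cm2
  smi <- compute_smi(measured_areas, cohort$height_m)
  pred <- classify_sarcopenia(smi, cutoff)
  roc <- roc_curve(smi, cohort$label)
  structure(list(report = screening_stats(pred, cohort$label, cutoff),
                 roc = roc, auc = auc(roc), youden = youden_optimal(roc),
                 smi = smi),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  print(x$report)
  cat(sprintf("  AUC %.4f; Youden-optimal cutoff %.4g (J = %.3f)\n",
              x$auc, x$youden$cutoff, x$youden$J))
  invisible(x)
}
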