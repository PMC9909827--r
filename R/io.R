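#' Read a CT volume from a NIfTI file
#'
#' Pixel spacing and slice thickness are taken from the NIfTI header pixdim
#' unless overridden. Only NIfTI input is supported.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param pixel_spacing optional (row, col) mm override.
#' @param slice_thickness optional mm override.
#' @param superior_first is the first stored slice the most superior?
#' @return a [ct_volume()].
#' @export
read_ct_volume <- function(path, pixel_spacing = NULL, slice_thickness = NULL,
                           superior_first = TRUE) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume")
  pd <- RNifti::pixdim(img)
  if (is.null(pixel_spacing)) pixel_spacing <- pd[1:2]
  if (is.null(slice_thickness)) slice_thickness <- pd[3]
  if (any(!is.finite(c(pixel_spacing, slice_thickness))) ||
      any(c(pixel_spacing, slice_thickness) <= 0))
    stop("geometry missing from header; pass pixel_spacing/slice_thickness")
  ct_volume(arr, pixel_spacing = pixel_spacing,
            slice_thickness = slice_thickness,
            superior_first = superior_first)
}

#' Write a CT volume to NIfTI
#'
#' @param volume a `ct_volume`.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
write_ct_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$slices)
  RNifti::pixdim(img) <- c(volume$pixel_spacing, volume$slice_thickness)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a mask stack to NIfTI with a channel-order sidecar
#'
#' Masks are stored as a 4D (H, W, n_slices, 3) volume; a JSON sidecar
#' records the channel order so channels cannot be swapped silently.
#'
#' @param masks list of (H, W, 3) binary arrays.
#' @param path output NIfTI path; the sidecar is `<path>.json`.
#' @return the path, invisibly.
#' @export
write_masks <- function(masks, path) {
  d <- dim(masks[[1]])
  arr <- array(0L, dim = c(d[1], d[2], length(masks), 3))
  for (i in seq_along(masks)) arr[, , i, ] <- masks[[i]]
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  jsonlite::write_json(list(channels = c("subq", "visceral", "muscle")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a mask stack written by [write_masks()]
#'
#' @param path NIfTI path.
#' @return list of (H, W, 3) integer arrays.
#' @export
read_masks <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) != 4L) stop("expected a 4D mask volume")
  lapply(seq_len(dim(arr)[3]), function(i) {
    m <- arr[, , i, , drop = FALSE]
    array(as.integer(m != 0), dim = dim(arr)[c(1, 2, 4)])
  })
}

#' Write a synthetic cohort table to CSV
#' @param cohort a [generate_cohort()] data frame.
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#' @param path CSV with columns patient_id, height_m, muscle_area_cm2, ...
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "height_m", "muscle_area_cm2")
  if (!all(need %in% names(df)))
    stop("cohort CSV must contain: ", paste(need, collapse = ", "))
  if ("label" %in% names(df)) df$label <- as.logical(df$label)
  df
}

#' Save a trained segmentation fit
#'
#' The checkpoint bundles the weights, the network/training configuration
#' and the package version.
#'
#' @param fit a `seg_fit` (or `seg_network`).
#' @param path output path (.rds).
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(list(format_version = 1L,
               package_version = as.character(utils::packageVersion("bodycomp")),
               object = fit),
          path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path checkpoint path.
#' @return the stored `seg_fit` / `seg_network`.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (is.null(x$format_version)) stop("not a bodycomp checkpoint")
  x$object
}
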