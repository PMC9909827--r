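#' CT volume container
#'
#' An ordered stack of axial slices with physical geometry. Slice index 1 is
#' the most superior slice ("top"); set `superior_first = FALSE` if the
#' source stored the stack the other way, and the constructor will reverse
#' it.
#'
#' @param slices 3D numeric array (H, W, n_slices) of HU values.
#' @param pixel_spacing in-plane spacing (row, col) in mm.
#' @param slice_thickness distance between adjacent slice centers, mm
#'   (default 5).
#' @param superior_first is slice 1 the most superior slice?
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(slices, pixel_spacing = c(1, 1), slice_thickness = 5,
                      superior_first = TRUE) {
  if (length(dim(slices)) != 3L) stop("slices must be a 3D array")
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2)
  if (any(pixel_spacing <= 0) || slice_thickness <= 0)
    stop("spacing and thickness must be positive")
  if (!superior_first) slices <- slices[, , rev(seq_len(dim(slices)[3]))]
  structure(list(slices = slices, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("<ct_volume> %d x %d x %d slices, %.3g x %.3g mm pixels, %.3g mm thickness\n",
              d[1], d[2], d[3], x$pixel_spacing[1], x$pixel_spacing[2],
              x$slice_thickness))
  invisible(x)
}

#' Number of slices in a CT volume
#' @param volume a `ct_volume`.
#' @export
n_slices <- function(volume) dim(volume$slices)[3]

#' Physical area of a binary mask plane
#'
#' Pixel-count area: `count * row_spacing * col_spacing / 100` cm².
#'
#' @param mask_plane binary matrix.
#' @param pixel_spacing (row, col) spacing in mm (scalar = isotropic).
#' @return area in cm².
#' @export
mask_area <- function(mask_plane, pixel_spacing = c(1, 1)) {
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2)
  if (any(pixel_spacing <= 0)) stop("pixel spacing must be positive")
  sum(mask_plane != 0) * pixel_spacing[1] * pixel_spacing[2] / 100
}

#' Volume of the slab between two adjacent slices
#'
#' Trapezoidal approximation `(S1 + S2) * H / 2`: the body is continuous
#' between adjacent slices and the slab is thin.
#'
#' @param S1,S2 areas of the two adjacent slices, cm².
#' @param H slice spacing in cm.
#' @return slab volume in cm³.
#' @export
slab_volume <- function(S1, S2, H) {
  if (S1 < 0 || S2 < 0 || H <= 0) stop("areas must be >= 0 and H > 0")
  (S1 + S2) * H / 2
}

#' Trapezoidal volume of an ordered stack of slice areas
#'
#' @param areas ordered per-slice areas, cm² (length >= 2).
#' @param H slice spacing in cm.
#' @return total volume in cm³.
#' @export
stack_volume <- function(areas, H) {
  if (length(areas) < 2) stop("need at least 2 slice areas")
  sum(vapply(seq_len(length(areas) - 1L),
             function(i) slab_volume(areas[i], areas[i + 1L], H), 0))
}

#' Truncate a CT stack to the abdominal window
#'
#' Drops the top 10% and bottom 30% of slices (floor on both counts),
#' retaining the middle ~60% where the abdomen lies. "Top" is the superior
#' end (slice 1).
#'
#' @param volume a `ct_volume` with >= 10 slices.
#' @return the truncated `ct_volume`.
#' @export
abdomen_window <- function(volume) {
  n <- n_slices(volume)
  if (n < 10L) stop("need >= 10 slices to truncate")
  lo <- floor(0.10 * n) + 1L
  hi <- n - floor(0.30 * n)
  if (lo > hi) stop("truncation leaves no slices")
  volume$slices <- volume$slices[, , lo:hi, drop = FALSE]
  volume
}

#' Extract the 41-slice window centered on the L3 slice
#'
#' Twenty slices above and twenty below the given L3 slice, 41 in total.
#'
#' @param volume a `ct_volume`.
#' @param l3_index 1-based index of the L3 slice.
#' @param half number of slices on each side (default 20).
#' @return `ct_volume` of 2*half+1 slices.
#' @export
l3_window <- function(volume, l3_index, half = 20L) {
  n <- n_slices(volume)
  lo <- l3_index - half; hi <- l3_index + half
  if (lo < 1L || hi > n)
    stop(sprintf("L3 window [%d, %d] exceeds volume extent [1, %d]", lo, hi, n))
  volume$slices <- volume$slices[, , lo:hi, drop = FALSE]
  volume
}

#' Difference and percent difference between measured volumes
#'
#' `difference = predicted - ground_truth`; the percentage is taken relative
#' to the predicted value: `100 * difference / predicted`.
#'
#' @param ground_truth reference volume, cm³.
#' @param predicted automatic volume, cm³ (nonzero).
#' @return list with `difference` (cm³) and `percent` (%).
#' @export
percent_difference <- function(ground_truth, predicted) {
  if (any(predicted == 0)) stop("predicted volume must be nonzero")
  d <- predicted - ground_truth
  list(difference = d, percent = 100 * d / predicted)
}

#' Quantify tissue areas and volumes from a mask stack
#'
#' @param masks list of (H, W, 3) binary arrays, one per slice, channel
#'   order (subq, visceral, muscle).
#' @param pixel_spacing in-plane spacing, mm.
#' @param slice_thickness slice spacing, mm.
#' @return list: `areas` (n x 3 matrix, cm²) and `volumes` (named length-3,
#'   cm³; trapezoidal over the stack).
#' @export
quantify_masks <- function(masks, pixel_spacing = c(1, 1),
                           slice_thickness = 5) {
  tissues <- c("subq", "visceral", "muscle")
  areas <- t(vapply(masks, function(m)
    vapply(1:3, function(k) mask_area(m[, , k], pixel_spacing), 0), numeric(3)))
  colnames(areas) <- tissues
  H_cm <- slice_thickness / 10
  vols <- if (length(masks) >= 2)
    apply(areas, 2, stack_volume, H = H_cm)
  else setNames(rep(NA_real_, 3), tissues)
  list(areas = areas, volumes = vols)
}
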