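#' Specification of a 2D abdominal CT phantom slice
#'
#' The phantom is an elliptical abdominal cross-section: a subcutaneous-fat
#' ring on the outside, a muscle wall inside it, and a visceral cavity
#' containing circular visceral-fat blobs. Tissue HU means follow standard CT
#' ranges (fat about -100, muscle about +40, air -1000); the cavity interior
#' sits near water (+20) so muscle/fat contrast resembles real scans.
#'
#' @param body_axes ellipse semi-axes (a, b) in mm.
#' @param subq_thickness subcutaneous fat ring thickness, mm.
#' @param muscle_thickness muscle wall thickness, mm.
#' @param visceral_blob_count number of visceral fat blobs.
#' @param visceral_blob_radius_range min/max blob radius, mm.
#' @param hu_means named numeric: HU mean per region
#'   (background, subq, muscle, interior, visceral).
#' @param hu_noise_sd additive Gaussian noise SD in HU.
#' @param pixel_spacing isotropic pixel size, mm.
#' @param image_size image side length in pixels (>= 32).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_axes = c(120, 90), subq_thickness = 15,
                         muscle_thickness = 12, visceral_blob_count = 3L,
                         visceral_blob_radius_range = c(8, 20),
                         hu_means = c(background = -1000, subq = -100,
                                      muscle = 40, interior = 20,
                                      visceral = -100),
                         hu_noise_sd = 10, pixel_spacing = 1,
                         image_size = 128L) {
  if (subq_thickness + muscle_thickness >= min(body_axes))
    stop("ring thicknesses exceed body axes")
  if (any(visceral_blob_radius_range <= 0)) stop("blob radii must be positive")
  if (image_size < 32L) stop("image_size must be >= 32")
  if (pixel_spacing <= 0) stop("pixel_spacing must be positive")
  structure(list(body_axes = body_axes, subq_thickness = subq_thickness,
                 muscle_thickness = muscle_thickness,
                 visceral_blob_count = as.integer(visceral_blob_count),
                 visceral_blob_radius_range = visceral_blob_radius_range,
                 hu_means = hu_means, hu_noise_sd = hu_noise_sd,
                 pixel_spacing = pixel_spacing,
                 image_size = as.integer(image_size)),
            class = "phantom_spec")
}

# draw non-overlapping blob centers/radii inside the visceral cavity
draw_blobs <- function(spec) {
  inner <- spec$body_axes - spec$subq_thickness - spec$muscle_thickness
  n <- spec$visceral_blob_count
  if (n == 0L) return(data.frame(x = numeric(), y = numeric(), r = numeric()))
  rr <- spec$visceral_blob_radius_range
  blobs <- data.frame(x = numeric(), y = numeric(), r = numeric())
  tries <- 0L
  while (nrow(blobs) < n && tries < 2000L) {
    tries <- tries + 1L
    r <- runif(1, rr[1], min(rr[2], 0.45 * min(inner)))
    # center inside the cavity ellipse shrunk by r so the blob fits entirely
    ax <- inner - r
    if (any(ax <= 0)) next
    repeat {
      x <- runif(1, -ax[1], ax[1]); y <- runif(1, -ax[2], ax[2])
      if ((x / ax[1])^2 + (y / ax[2])^2 <= 1) break
    }
    if (nrow(blobs) == 0 ||
        all(sqrt((blobs$x - x)^2 + (blobs$y - y)^2) > blobs$r + r + 1)) {
      blobs <- rbind(blobs, data.frame(x = x, y = y, r = r))
    }
  }
  blobs
}

in_ellipse <- function(px, py, ax) (px / ax[1])^2 + (py / ax[2])^2 <= 1

#' Generate one phantom CT slice with analytic ground truth
#'
#' Pixel membership is decided at pixel centers; the returned mask is binary
#' per channel with channels (subcutaneous fat, visceral fat, muscle),
#' pairwise disjoint. Analytic areas are exact ellipse-ring and disc areas in
#' cm². Identical seeds reproduce the slice bit for bit.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @param blobs optional precomputed blob layout (data frame x, y, r in mm);
#'   used by [generate_volume()] to keep blob positions coherent across
#'   slices.
#' @return list: `image` (HU matrix), `mask` (H x W x 3 binary array),
#'   `analytic_areas` (named cm²: subq, visceral, muscle).
#' @export
generate_slice <- function(spec, seed = 1L, blobs = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(seed)
  if (is.null(blobs)) blobs <- draw_blobs(spec)
  n <- spec$image_size
  sp <- spec$pixel_spacing
  # pixel-center coordinates in mm, origin at image center
  coords <- (seq_len(n) - (n + 1) / 2) * sp
  px <- matrix(coords, n, n)        # row coordinate
  py <- matrix(coords, n, n, byrow = TRUE)
  a0 <- spec$body_axes
  a1 <- a0 - spec$subq_thickness
  a2 <- a1 - spec$muscle_thickness
  body <- in_ellipse(px, py, a0)
  musc_out <- in_ellipse(px, py, a1)
  cavity <- in_ellipse(px, py, a2)
  subq <- body & !musc_out
  muscle <- musc_out & !cavity
  visceral <- matrix(FALSE, n, n)
  if (nrow(blobs) > 0) {
    for (bi in seq_len(nrow(blobs))) {
      visceral <- visceral |
        ((px - blobs$x[bi])^2 + (py - blobs$y[bi])^2 <= blobs$r[bi]^2)
    }
    visceral <- visceral & cavity
  }
  interior <- cavity & !visceral
  hu <- spec$hu_means
  image <- matrix(hu[["background"]], n, n)
  image[subq] <- hu[["subq"]]
  image[muscle] <- hu[["muscle"]]
  image[interior] <- hu[["interior"]]
  image[visceral] <- hu[["visceral"]]
  if (spec$hu_noise_sd > 0)
    image <- image + matrix(rnorm(n * n, sd = spec$hu_noise_sd), n, n)
  mask <- array(0L, dim = c(n, n, 3))
  mask[, , 1] <- subq + 0L
  mask[, , 2] <- visceral + 0L
  mask[, , 3] <- muscle + 0L
  areas <- c(subq = pi * (prod(a0) - prod(a1)),
             visceral = sum(pi * blobs$r^2),
             muscle = pi * (prod(a1) - prod(a2))) / 100  # mm² -> cm²
  list(image = image, mask = mask, analytic_areas = areas, blobs = blobs)
}

#' Specification of a phantom CT volume
#'
#' @param base a [phantom_spec()] for the reference slice.
#' @param n_slices number of slices (>= 2).
#' @param slice_thickness slice spacing in mm (default 5).
#' @param axis_profile per-slice multiplicative scaling of the body axes:
#'   numeric vector of length `n_slices` (smooth profiles give smoothly
#'   varying areas). Default: constant 1.
#' @return object of class `phantom_volume_spec`.
#' @export
phantom_volume_spec <- function(base = phantom_spec(), n_slices = 41L,
                                slice_thickness = 5,
                                axis_profile = rep(1, n_slices)) {
  if (n_slices < 2L) stop("n_slices must be >= 2: a volume needs adjacent slices")
  if (slice_thickness <= 0) stop("slice_thickness must be positive")
  if (length(axis_profile) != n_slices)
    stop("axis_profile length must equal n_slices")
  structure(list(base = base, n_slices = as.integer(n_slices),
                 slice_thickness = slice_thickness,
                 axis_profile = axis_profile),
            class = "phantom_volume_spec")
}

#' Generate a phantom CT volume with per-slice ground truth
#'
#' Body axes, ring thicknesses and the (once-drawn) visceral blob layout are
#' all scaled by the per-slice `axis_profile` factor, so analytic areas vary
#' smoothly along the stack (each scales with factor²).
#'
#' @param vspec a [phantom_volume_spec()].
#' @param seed integer seed.
#' @return list: `volume` (a [ct_volume()]), `masks` (list of H x W x 3
#'   arrays), `analytic_areas` (n_slices x 3 matrix, cm²).
#' @export
generate_volume <- function(vspec, seed = 1L) {
  stopifnot(inherits(vspec, "phantom_volume_spec"))
  base <- vspec$base
  set.seed(seed)
  blobs0 <- draw_blobs(base)
  n <- vspec$n_slices
  imgs <- vector("list", n); masks <- vector("list", n)
  areas <- matrix(NA_real_, n, 3,
                  dimnames = list(NULL, c("subq", "visceral", "muscle")))
  for (i in seq_len(n)) {
    f <- vspec$axis_profile[i]
    spec_i <- base
    spec_i$body_axes <- base$body_axes * f
    spec_i$subq_thickness <- base$subq_thickness * f
    spec_i$muscle_thickness <- base$muscle_thickness * f
    blobs_i <- blobs0
    if (nrow(blobs_i) > 0) {
      blobs_i$x <- blobs_i$x * f; blobs_i$y <- blobs_i$y * f
      blobs_i$r <- blobs_i$r * f
    }
    sl <- generate_slice(spec_i, seed = seed + i, blobs = blobs_i)
    imgs[[i]] <- sl$image
    masks[[i]] <- sl$mask
    areas[i, ] <- sl$analytic_areas
  }
  vol <- ct_volume(array(unlist(imgs),
                         dim = c(base$image_size, base$image_size, n)),
                   pixel_spacing = rep(base$pixel_spacing, 2),
                   slice_thickness = vspec$slice_thickness)
  list(volume = vol, masks = masks, analytic_areas = areas)
}

#' Specification of a synthetic screening cohort
#'
#' Defaults emulate a female screening population: height 1.591 +/- 0.059 m
#' and a sarcopenia prevalence near 38.3%.
#'
#' @param n_patients cohort size.
#' @param height_mean_sd mean and SD of height in m.
#' @param muscle_area_mean_sd mean and SD of L3 muscle area in cm².
#' @param prevalence_target fraction of sarcopenic patients in (0, 1).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 264L, height_mean_sd = c(1.591, 0.059),
                        muscle_area_mean_sd = c(100, 15),
                        prevalence_target = 0.383) {
  if (prevalence_target <= 0 || prevalence_target >= 1)
    stop("prevalence_target must be in (0,1)")
  if (any(height_mean_sd <= 0)) stop("height parameters must be positive")
  structure(list(n_patients = as.integer(n_patients),
                 height_mean_sd = height_mean_sd,
                 muscle_area_mean_sd = muscle_area_mean_sd,
                 prevalence_target = prevalence_target),
            class = "cohort_spec")
}

#' Generate a synthetic screening cohort with planted sarcopenia labels
#'
#' Heights and L3 muscle areas are drawn from the stated normal
#' distributions; areas are then rescaled so the empirical fraction of
#' patients with true SMI below `planted_cutoff` matches the prevalence
#' target (scaling the area distribution, not relabeling). Labels are exact:
#' `sarcopenia = (true_smi < planted_cutoff)`. With `planted_cutoff = 0`
#' no rescaling is possible and no patient is sarcopenic (a warning is
#' issued if the target prevalence is thereby unreachable).
#'
#' Subcutaneous and visceral fat areas are included as correlated nuisance
#' measurements so cohort tables have the full column set.
#'
#' @param cspec a [cohort_spec()].
#' @param planted_cutoff SMI threshold in cm²/m² defining the true labels
#'   (default 38.5, the accepted female cutoff).
#' @param seed integer seed.
#' @return data frame of class `synthetic_cohort`: patient_id, height_m,
#'   muscle_area_cm2, subq_area_cm2, visceral_area_cm2, smi, label (logical).
#' @export
generate_cohort <- function(cspec, planted_cutoff = 38.5, seed = 1L) {
  stopifnot(inherits(cspec, "cohort_spec"))
  set.seed(seed)
  n <- cspec$n_patients
  h <- rnorm(n, cspec$height_mean_sd[1], cspec$height_mean_sd[2])
  h <- pmin(pmax(h, 1.30), 2.10)
  area <- rnorm(n, cspec$muscle_area_mean_sd[1], cspec$muscle_area_mean_sd[2])
  area <- pmax(area, 20)
  smi <- area / h^2
  if (planted_cutoff > 0) {
    q <- quantile(smi, probs = cspec$prevalence_target, type = 1)
    f <- planted_cutoff / as.numeric(q)
    area <- area * f
    smi <- smi * f
  }
  label <- smi < planted_cutoff
  prev <- mean(label)
  se <- sqrt(cspec$prevalence_target * (1 - cspec$prevalence_target) / n)
  if (abs(prev - cspec$prevalence_target) > 3 * se + 1 / n)
    warning(sprintf("achieved prevalence %.3f misses target %.3f", prev,
                    cspec$prevalence_target))
  out <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    height_m = h,
    muscle_area_cm2 = area,
    subq_area_cm2 = pmax(rnorm(n, 180, 50), 30),
    visceral_area_cm2 = pmax(rnorm(n, 110, 45), 10),
    smi = smi,
    label = label)
  class(out) <- c("synthetic_cohort", "data.frame")
  out
}
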