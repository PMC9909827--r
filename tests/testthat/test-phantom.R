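test_that("slice generation is deterministic and validates its spec", {
  sp <- tiny_spec()
  a <- generate_slice(sp, seed = 11)
  b <- generate_slice(sp, seed = 11)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c <- generate_slice(sp, seed = 12)
  expect_false(identical(a$mask, c$mask))
  expect_error(phantom_spec(body_axes = c(20, 20), subq_thickness = 15,
                            muscle_thickness = 12),
               "exceed")
  expect_error(phantom_spec(image_size = 16), "32")
  expect_error(phantom_spec(visceral_blob_radius_range = c(-1, 5)),
               "positive")
})

test_that("mask channels are disjoint, inside the body, and match analytic areas", {
  for (seed in 1:5) {
    sp <- phantom_spec(image_size = 128L, pixel_spacing = 2,
                       body_axes = c(110, 85), subq_thickness = 15,
                       muscle_thickness = 12, hu_noise_sd = 5,
                       visceral_blob_count = 3L)
    sl <- generate_slice(sp, seed = seed)
    m <- sl$mask
    expect_true(all(m %in% c(0L, 1L)))
    overlap <- m[, , 1] * m[, , 2] + m[, , 1] * m[, , 3] + m[, , 2] * m[, , 3]
    expect_equal(sum(overlap), 0)
    # every foreground pixel lies in the body ellipse (subq outer boundary)
    n <- sp$image_size
    coords <- (seq_len(n) - (n + 1) / 2) * sp$pixel_spacing
    px <- matrix(coords, n, n); py <- matrix(coords, n, n, byrow = TRUE)
    body <- (px / sp$body_axes[1])^2 + (py / sp$body_axes[2])^2 <= 1
    expect_true(all((m[, , 1] | m[, , 2] | m[, , 3])[!body] == 0))
    for (k in 1:3) {
      pix <- mask_area(m[, , k], sp$pixel_spacing)
      expect_lt(abs(pix - sl$analytic_areas[k]) / sl$analytic_areas[k], 0.05)
    }
  }
})

test_that("subcutaneous pixel area matches the analytic ellipse annulus within 2%", {
  sp <- phantom_spec(image_size = 256L, pixel_spacing = 1,
                     body_axes = c(120, 90), subq_thickness = 15,
                     muscle_thickness = 12, hu_noise_sd = 0)
  sl <- generate_slice(sp, seed = 3)
  analytic <- pi * (120 * 90 - 105 * 75) / 100          # cm²
  expect_equal(sl$analytic_areas[["subq"]], analytic)
  pix <- mask_area(sl$mask[, , 1], 1)
  expect_lt(abs(pix - analytic) / analytic, 0.02)
})

test_that("rasterization error shrinks roughly in proportion to pixel size", {
  # the error for any single geometry oscillates with grid alignment, so
  # average over several geometries to expose the O(h) trend
  mean_err <- function(spacing, size) {
    es <- vapply(1:8, function(i) {
      sp <- phantom_spec(image_size = size, pixel_spacing = spacing,
                         body_axes = c(100, 80) * (0.85 + 0.03 * i),
                         subq_thickness = 15, muscle_thickness = 12,
                         hu_noise_sd = 0, visceral_blob_count = 0L)
      sl <- generate_slice(sp, seed = i)
      abs(mask_area(sl$mask[, , 3], spacing) - sl$analytic_areas[["muscle"]])
    }, 0)
    mean(es)
  }
  e2 <- mean_err(2, 128L)
  e1 <- mean_err(1, 256L)
  e05 <- mean_err(0.5, 512L)
  expect_lt(e1, e2)
  expect_lt(e05, e1)
  expect_lt(e05, e2 / 2)             # at least first-order overall
})

test_that("zero blob count gives an empty visceral compartment", {
  sl <- generate_slice(tiny_spec(visceral_blob_count = 0L), seed = 1)
  expect_equal(sum(sl$mask[, , 2]), 0)
  expect_equal(sl$analytic_areas[["visceral"]], 0)
})

test_that("volume generation follows the axis profile", {
  base <- tiny_spec()
  expect_error(phantom_volume_spec(base, n_slices = 1), ">= 2")
  # constant profile: identical analytic areas on every slice
  vs <- phantom_volume_spec(base, n_slices = 5, slice_thickness = 5)
  gv <- generate_volume(vs, seed = 2)
  expect_equal(n_slices(gv$volume), 5)
  expect_true(all(abs(gv$analytic_areas[, "muscle"] -
                      gv$analytic_areas[1, "muscle"]) < 1e-12))
  # linear profile: areas scale with factor² and are monotone
  prof <- seq(0.8, 1.1, length.out = 6)
  gvl <- generate_volume(phantom_volume_spec(base, n_slices = 6,
                                             axis_profile = prof), seed = 2)
  expect_true(all(diff(gvl$analytic_areas[, "subq"]) > 0))
  expect_equal(as.numeric(gvl$analytic_areas[6, "subq"] /
                            gvl$analytic_areas[1, "subq"]),
               (prof[6] / prof[1])^2, tolerance = 1e-10)
  # physical extent between first and last slice centers
  vs41 <- phantom_volume_spec(base, n_slices = 41, slice_thickness = 5)
  expect_equal((vs41$n_slices - 1) * vs41$slice_thickness, 200)
})

test_that("cohort generation plants labels consistently and hits prevalence", {
  cs <- cohort_spec(n_patients = 1000L, prevalence_target = 0.40)
  coh <- generate_cohort(cs, planted_cutoff = 38.5, seed = 9)
  expect_equal(coh$smi, coh$muscle_area_cm2 / coh$height_m^2)
  expect_identical(coh$label, coh$smi < 38.5)
  expect_gte(mean(coh$label), 0.37)
  expect_lte(mean(coh$label), 0.43)
  # reproducibility
  coh2 <- generate_cohort(cs, planted_cutoff = 38.5, seed = 9)
  expect_identical(coh, coh2)
  # impossible threshold: nobody is sarcopenic
  coh0 <- suppressWarnings(generate_cohort(cs, planted_cutoff = 0, seed = 9))
  expect_equal(sum(coh0$label), 0)
})

test_that("cohort defaults emulate the screening population", {
  coh <- generate_cohort(cohort_spec(n_patients = 2000L), seed = 4)
  expect_equal(mean(coh$height_m), 1.591, tolerance = 0.01)
  expect_equal(sd(coh$height_m), 0.059, tolerance = 0.15)
  expect_equal(mean(coh$label), 0.383, tolerance = 0.02)
})
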