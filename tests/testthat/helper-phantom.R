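# Shared builders for phantom training samples used across tests.

# Varied 64x64 phantom slices (anatomy randomized per seed) as
# list(image, mask) samples ready for train_model().
make_phantom_samples <- function(seeds, image_size = 64L) {
  lapply(seeds, function(s) {
    set.seed(s)
    sp <- phantom_spec(image_size = image_size, pixel_spacing = 3.5,
                       body_axes = c(100, 80) * runif(1, 0.8, 1.15),
                       subq_thickness = 14 * runif(1, 0.7, 1.3),
                       muscle_thickness = 11 * runif(1, 0.7, 1.3),
                       visceral_blob_count = sample(1:5, 1),
                       visceral_blob_radius_range = c(9, 22),
                       hu_noise_sd = 10)
    sl <- generate_slice(sp, seed = s)
    list(image = sl$image, mask = sl$mask)
  })
}

# tiny deterministic spec for fast structural tests
tiny_spec <- function(...) {
  args <- list(image_size = 32L, pixel_spacing = 7,
               body_axes = c(100, 80), subq_thickness = 15,
               muscle_thickness = 12, visceral_blob_count = 2L,
               visceral_blob_radius_range = c(10, 18), hu_noise_sd = 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_spec, args)
}
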