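## small, quick synthetic leaves shared across test files
small_leaf_spec <- function(seed = 1, width_mm = 2, height_mm = 2,
                            density = 80, tip = density, vein_count = 1,
                            ...) {
  synthetic_leaf_spec(width_mm = width_mm, height_mm = height_mm,
                      base_density_mm2 = density, tip_density_mm2 = tip,
                      vein_count = vein_count, seed = seed, ...)
}

## uniform-noise image with no objects at all
noise_image <- function(seed = 1, n = 600, level = 30000, sd = 3000,
                        pixel_size_um = 1.11) {
  set.seed(seed)
  px <- pmin(pmax(round(level + sd * rnorm(n * n)), 0), 65535)
  leaf_image(matrix(px, n, n), pixel_size_um = pixel_size_um, bit_depth = 16L)
}
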