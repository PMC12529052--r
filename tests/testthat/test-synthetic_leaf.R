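test_that("spec validation rejects degenerate geometry", {
  expect_error(synthetic_leaf_spec(width_mm = 0), "positive")
  expect_error(synthetic_leaf_spec(stoma_major_um = 5000, width_mm = 4),
               "larger than the image")
  expect_error(synthetic_leaf_spec(file_spacing_um = 10),
               "file_spacing_um")
  expect_error(synthetic_leaf_spec(stoma_intensity_frac = 1),
               "stoma_intensity_frac")
  expect_error(synthetic_leaf_spec(base_density_mm2 = -1), "non-negative")
  ## stoma area outside the detectable window is rejected when labelled so
  expect_error(synthetic_leaf_spec(stoma_major_um = 30, stoma_minor_um = 20,
                                   file_spacing_um = 40),
               "detectable")
  expect_s3_class(synthetic_leaf_spec(stoma_major_um = 30,
                                      stoma_minor_um = 20,
                                      file_spacing_um = 40,
                                      detectable = FALSE),
                  "synthetic_leaf_spec")
  ## density infeasible under the hard-core spacing
  expect_error(generate_leaf_image(small_leaf_spec(density = 400)),
               "density too high")
})

test_that("zero-density spec yields an empty ground truth", {
  leaf <- generate_leaf_image(small_leaf_spec(width_mm = 1, height_mm = 1,
                                              density = 0))
  expect_identical(nrow(leaf$truth), 0L)
  expect_true(all(leaf$image[!leaf$exclusion] > 0))
})

test_that("identical spec and seed give bit-identical output", {
  s <- small_leaf_spec(seed = 42, width_mm = 1.2, height_mm = 1.2)
  a <- generate_leaf_image(s)
  b <- generate_leaf_image(s)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$truth, b$truth)
  ## a different seed changes the realisation
  c <- generate_leaf_image(small_leaf_spec(seed = 43, width_mm = 1.2,
                                           height_mm = 1.2))
  expect_false(identical(a$truth, c$truth))
})

test_that("rendered counts follow the requested uniform density", {
  d <- 70
  for (seed in 1:20) {
    leaf <- generate_leaf_image(small_leaf_spec(seed = seed, width_mm = 1.5,
                                                height_mm = 1.5, density = d))
    expected <- d * leaf$available_mm2
    expect_lt(abs(nrow(leaf$truth) - expected), 4 * sqrt(expected))
  }
})

test_that("ground-truth centroids avoid excluded regions and never overlap", {
  leaf <- generate_leaf_image(small_leaf_spec(seed = 7, density = 100))
  px <- pixel_size(leaf$image)
  rr <- ceiling(leaf$truth$centroid_y_um / px)
  cc <- ceiling(leaf$truth$centroid_x_um / px)
  expect_false(any(leaf$exclusion[cbind(rr, cc)]))
  ## hard-core: along each file, centre gaps exceed the semi-axis sum
  spec <- leaf$spec
  for (k in unique(leaf$truth$row_index)) {
    xs <- sort(leaf$truth$centroid_x_um[leaf$truth$row_index == k])
    if (length(xs) > 1)
      expect_gt(min(diff(xs)), spec$stoma_major_um)
  }
  ## files are farther apart than the stoma minor axis
  ys <- sort(unique(leaf$truth$centroid_y_um))
  if (length(ys) > 1)
    expect_gt(min(diff(ys)), spec$stoma_minor_um)
})

test_that("image dtype and value range match the requested bit depth", {
  leaf16 <- generate_leaf_image(small_leaf_spec(width_mm = 1, height_mm = 1))
  expect_identical(bit_depth(leaf16$image), 16L)
  expect_true(is.integer(unclass(leaf16$image)))
  expect_true(max(leaf16$image) <= 65535 && min(leaf16$image) >= 0)
  leaf8 <- generate_leaf_image(small_leaf_spec(width_mm = 1, height_mm = 1,
                                               bit_depth = 8))
  expect_identical(bit_depth(leaf8$image), 8L)
  expect_true(max(leaf8$image) <= 255)
})

test_that("expected density field is the linear base-to-tip gradient", {
  flat <- synthetic_leaf_spec(width_mm = 3, height_mm = 3,
                              base_density_mm2 = 60, tip_density_mm2 = 60)
  f <- expected_density_field(flat)
  expect_true(all(abs(f[f > 0] - 60) < 1e-9))
  grad <- synthetic_leaf_spec(width_mm = 3, height_mm = 3,
                              base_density_mm2 = 40, tip_density_mm2 = 62)
  g <- expected_density_field(grad)
  ## the mid-leaf cell (centre at half the width) interpolates to 51
  expect_equal(unname(g[2, 2]), 51, tolerance = 1e-3)
})

test_that("analytic field integral matches the Monte Carlo mean count", {
  spec <- small_leaf_spec(width_mm = 1.5, height_mm = 1.5, density = 80,
                          tip = 100)
  field <- expected_density_field(spec)
  geom <- stomamap:::leaf_structure(spec)
  avail <- stomamap:::cell_available_area(geom$excl, spec$pixel_size_um, 1)
  expected_total <- sum(field * avail)
  counts <- vapply(1:50, function(s) {
    sp <- small_leaf_spec(seed = s, width_mm = 1.5, height_mm = 1.5,
                          density = 80, tip = 100)
    nrow(generate_leaf_image(sp)$truth)
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected_total), 3 * se + 1)
})

test_that("per-cell rendered counts match the expected field", {
  ## cell-wise comparison of the mean count over seeds against
  ## field x available area, within 3 standard errors (plus a sub-stoma
  ## allowance for the renewal process's residual half-gap lag at steps
  ## of the edge-correction factors)
  nseeds <- 30
  base <- small_leaf_spec(width_mm = 2.5, height_mm = 2.5, density = 60,
                          vein_count = 2)
  field <- expected_density_field(base)
  geom <- stomamap:::leaf_structure(base)
  avail <- stomamap:::cell_available_area(geom$excl, base$pixel_size_um, 1)
  expected <- field * avail
  acc <- array(0, dim = c(dim(expected), nseeds))
  for (s in seq_len(nseeds)) {
    sp <- small_leaf_spec(seed = s, width_mm = 2.5, height_mm = 2.5,
                          density = 60, vein_count = 2)
    leaf <- generate_leaf_image(sp)
    g <- grid_density(leaf$truth, extent_um = c(geom$W_um, geom$H_um),
                      pixel_size_um = base$pixel_size_um)
    acc[, , s] <- g$counts[seq_len(nrow(expected)), seq_len(ncol(expected))]
  }
  mean_counts <- apply(acc, c(1, 2), mean)
  se <- apply(acc, c(1, 2), sd) / sqrt(nseeds)
  compare <- avail > 0.1            # skip slivers with almost no area
  dev <- abs(mean_counts - expected)[compare]
  expect_true(all(dev < 3 * se[compare] + 0.5))
})

test_that("ground truth round-trips through CSV", {
  leaf <- generate_leaf_image(small_leaf_spec(width_mm = 1, height_mm = 1))
  p <- tempfile(fileext = ".csv")
  write_ground_truth(leaf$truth, p)
  back <- read_ground_truth(p)
  expect_equal(back, leaf$truth, tolerance = 1e-12)
  unlink(p)
})
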