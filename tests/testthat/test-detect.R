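px <- 1.11

## paint a filled ellipse (pixel-centre test) into a logical matrix
paint_ellipse <- function(mat, cx, cy, a, b) {
  for (r in seq_len(nrow(mat))) for (c in seq_len(ncol(mat))) {
    if (((c - 0.5 - cx)^2) / a^2 + ((r - 0.5 - cy)^2) / b^2 <= 1)
      mat[r, c] <- TRUE
  }
  mat
}

test_that("particle measurement recovers ellipse area and gates shapes", {
  rule <- threshold_rule("li")
  ## 2.5:1 ellipse of a stoma's size: retained, area close to pi*a*b
  bin <- paint_ellipse(matrix(FALSE, 120, 120), 60, 60, 30, 12)
  out <- find_particles(bin, px, rule)
  expect_identical(nrow(out), 1L)
  true_area <- pi * 30 * 12 * px^2
  expect_lt(abs(out$area_um2 - true_area) / true_area, 0.03)
  expect_true(out$circularity >= 0.5 && out$circularity <= 0.9)
  expect_lt(abs(out$centroid_x_um - 60 * px), px)
  expect_lt(abs(out$centroid_y_um - 60 * px), px)
  ## a near-perfect disk is rounder than the 0.9 ceiling and is rejected
  disk <- paint_ellipse(matrix(FALSE, 100, 100), 50, 50, 18, 18)
  expect_identical(nrow(find_particles(disk, px, rule)), 0L)
  feats <- stomamap:::particle_features(stomamap:::label_particles(disk), px)
  expect_gt(feats$circularity, 0.9)
  ## a 2-px speck is far below the 800 um^2 floor
  speck <- matrix(FALSE, 20, 20); speck[5, 5:6] <- TRUE
  expect_identical(nrow(find_particles(speck, px, rule)), 0L)
  ## a long thin 200 x 4 px rectangle fails circularity (4piA/P^2 ~ 0.1)
  rect <- matrix(FALSE, 220, 30); rect[10:209, 10:13] <- TRUE
  expect_identical(nrow(find_particles(rect, px, rule)), 0L)
  featr <- stomamap:::particle_features(stomamap:::label_particles(rect), px)
  expect_lt(featr$circularity, 0.5)
  expect_gt(featr$area_um2, 800)     # rejected by shape, not by size
})

test_that("labelling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE; m[4, 4] <- TRUE   # diagonal chain
  lab <- stomamap:::label_particles(m)
  expect_identical(max(lab), 1L)
  m[6, 6] <- TRUE                                     # separate object
  expect_identical(max(stomamap:::label_particles(m)), 2L)
})

test_that("detection on synthetic leaves meets recall and precision with
           every stored field satisfying its rule's gates", {
  for (seed in 1:3) {
    leaf <- generate_leaf_image(small_leaf_spec(seed = seed, density = 85))
    pre <- preprocess_image(leaf$image)
    mask <- exclusion_mask(pre)
    det <- detect_stomata(pre, mask = mask)
    v <- validate_against_truth(det, leaf$truth)
    expect_gt(v$recall, 0.9)
    expect_gt(v$precision, 0.9)
    ## detections are re-checkable against their originating rule
    rules <- threshold_rules()
    names(rules) <- vapply(rules, `[[`, character(1), "method")
    for (i in seq_len(nrow(det))) {
      r <- rules[[det$method[i]]]
      expect_true(det$area_um2[i] >= r$area_min_um2 &&
                    det$area_um2[i] <= r$area_max_um2)
      expect_true(det$circularity[i] >= r$circ_min &&
                    det$circularity[i] <= r$circ_max)
    }
    ## no detection centroid inside the exclusion mask
    rr <- ceiling(det$centroid_y_um / px); cc <- ceiling(det$centroid_x_um / px)
    expect_false(any(mask$mask[cbind(rr, cc)]))
  }
})

test_that("a pure-noise image yields an empty stoma set", {
  det <- suppressWarnings(detect_stomata(preprocess_image(noise_image())))
  expect_identical(nrow(det), 0L)
})

test_that("listing the same rule twice changes nothing (idempotent union)", {
  leaf <- generate_leaf_image(small_leaf_spec(seed = 5, width_mm = 1.5,
                                              height_mm = 1.5))
  pre <- preprocess_image(leaf$image)
  one <- detect_stomata(pre, rules = list(threshold_rule("li")))
  two <- detect_stomata(pre, rules = list(threshold_rule("li"),
                                          threshold_rule("li")))
  expect_equal(as.data.frame(one), as.data.frame(two), ignore_attr = TRUE)
  ## pooled count is an upper bound for the merged count
  all3 <- detect_stomata(pre)
  expect_lte(nrow(all3), sum(attr(all3, "n_per_rule")))
})

test_that("exclusion masking keeps large dark structures only", {
  ## dark vein stripe of 0.6 x 1.2 mm (720000 um^2) enters the mask
  set.seed(8)
  img <- matrix(30000 + round(rnorm(1100 * 700, 0, 1500)), 1100, 700)
  rows <- 301:841              # 541 px ~ 0.6 mm; columns span ~0.78 mm
  img[rows, ] <- round(7000 + rnorm(length(rows) * 700, 0, 800))
  limg <- leaf_image(pmin(pmax(img, 0), 65535))
  m <- exclusion_mask(limg)
  inside <- mean(m$mask[rows, ])
  expect_gt(inside, 0.9)
  expect_gt(m$excluded_area_um2, 400000)
  ## a *preprocessed* image whose only dark objects are stoma-sized
  ## ellipses: no component reaches the 400000 um^2 floor, mask empty
  img2 <- matrix(30000 + round(rnorm(900 * 900, 0, 1500)), 900, 900)
  for (cx in c(150, 450, 750)) {
    rr <- outer((1:900 - 0.5 - 450)^2 / 12^2,
                (1:900 - 0.5 - cx)^2 / 30^2, "+") <= 1
    img2[rr] <- 7000
  }
  pre2 <- preprocess_image(leaf_image(pmin(pmax(img2, 0), 65535)))
  m2 <- exclusion_mask(pre2)
  expect_identical(m2$excluded_area_um2, 0)
})

test_that("exclusion mask overlaps the generator's own vein raster", {
  leaf <- generate_leaf_image(small_leaf_spec(seed = 2, density = 80,
                                              vein_count = 2))
  m <- exclusion_mask(preprocess_image(leaf$image))
  iou <- sum(m$mask & leaf$exclusion) / sum(m$mask | leaf$exclusion)
  expect_gt(iou, 0.8)
})

test_that("stomatal density is count over available area", {
  expect_equal(stomatal_density(100, 2e6, 0.5e6), 100 / 1.5)
  expect_equal(stomatal_density(0, 5e6, 1e6), 0)
  expect_equal(stomatal_density(57, 1e6, 0), 57)
  expect_error(stomatal_density(1, 1e6, 1e6), "available area")
  expect_error(stomatal_density(1, 1e6, 2e6), "exceeds")
  ## padding consistency: extra excluded area leaves density unchanged
  expect_equal(stomatal_density(120, 2e6, 0.2e6),
               stomatal_density(120, 3e6, 1.2e6))
})
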