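random_grid <- function(nr, nc, seed = 1, mu = 80, sigma = 20) {
  set.seed(seed)
  density_grid_from_matrix(matrix(rnorm(nr * nc, mu, sigma), nr, nc))
}

test_that("k-NN weights recover rook neighbours inside a full grid and
           break corner ties by row-major index", {
  g <- random_grid(5, 5)
  w <- knn_weights(g, 4)
  expect_identical(w$W, w$n * 4L)
  expect_true(all(w$neighbors != seq_len(w$n)))   # no self-neighbours
  ## interior cell (3,3) is valid-cell 13 in row-major order: N, W, E, S
  centre <- which(w$cell_rc[, "row"] == 3 & w$cell_rc[, "col"] == 3)
  nb_rc <- w$cell_rc[w$neighbors[centre, ], , drop = FALSE]
  expect_setequal(paste(nb_rc[, 1], nb_rc[, 2]),
                  c("2 3", "4 3", "3 2", "3 4"))
  ## corner (1,1): two rook cells at distance 1, diagonal at sqrt(2), and a
  ## tie at distance 2 between (1,3) and (3,1) resolved to (1,3) (smaller
  ## row-major index)
  corner <- which(w$cell_rc[, "row"] == 1 & w$cell_rc[, "col"] == 1)
  nb_rc <- w$cell_rc[w$neighbors[corner, ], , drop = FALSE]
  expect_setequal(paste(nb_rc[, 1], nb_rc[, 2]),
                  c("1 2", "2 1", "2 2", "1 3"))
})

test_that("k-NN weights skip invalid cells, matching brute-force search", {
  m <- matrix(rnorm(36, 70, 10), 6, 6)
  m[3, 3] <- NA; m[3, 4] <- NA; m[4, 3] <- NA      # masked hole
  g <- density_grid_from_matrix(m)
  w <- knn_weights(g, 4)
  idx <- w$cell_index
  cx <- (w$cell_rc[, "col"] - 0.5); cy <- (w$cell_rc[, "row"] - 0.5)
  expect_identical(w$neighbors, oracle_knn(cx, cy, idx, 4))
  expect_error(knn_weights(density_grid_from_matrix(matrix(1:4, 2, 2)), 4),
               "more than k")
})

test_that("global and local Moran's I equal the nested-loop oracles on
           grids up to 8 x 8", {
  shapes <- list(c(3, 3), c(4, 4), c(5, 3), c(6, 6), c(8, 8), c(8, 3))
  for (i in seq_along(shapes)) {
    g <- random_grid(shapes[[i]][1], shapes[[i]][2], seed = i)
    w <- knn_weights(g, 4)
    v <- g$sd[cbind(w$cell_rc[, "row"], w$cell_rc[, "col"])]
    expect_equal(global_morans_i(g, w), oracle_global_moran(v, w$neighbors),
                 tolerance = 1e-12)
    li <- local_morans_i(g, w)
    expect_equal(li[cbind(w$cell_rc[, "row"], w$cell_rc[, "col"])],
                 oracle_local_moran(v, w$neighbors), tolerance = 1e-12)
    ## algebraic identity: I = (n/W) * sum(I_i) / sum(z^2)
    z <- v - mean(v)
    expect_equal(global_morans_i(g, w),
                 (w$n / w$W) * sum(li, na.rm = TRUE) / sum(z^2),
                 tolerance = 1e-12)
  }
  ## 3x3 grid with values 1..9 row-major against the explicit double sum
  g9 <- density_grid_from_matrix(matrix(1:9, 3, 3, byrow = TRUE))
  w9 <- knn_weights(g9, 4)
  v9 <- g9$sd[cbind(w9$cell_rc[, "row"], w9$cell_rc[, "col"])]
  expect_equal(global_morans_i(g9, w9),
               oracle_global_moran(v9, w9$neighbors), tolerance = 1e-12)
})

test_that("Moran's I agrees with an independent library implementation", {
  g <- random_grid(6, 6, seed = 9)
  w <- knn_weights(g, 4)
  v <- g$sd[cbind(w$cell_rc[, "row"], w$cell_rc[, "col"])]
  wmat <- matrix(0, w$n, w$n)
  for (i in seq_len(w$n)) wmat[i, w$neighbors[i, ]] <- 1
  ## ape row-normalises; with equal row sums (k each) the statistic is
  ## identical to the binary-weight form
  expect_equal(global_morans_i(g, w),
               ape::Moran.I(v, wmat)$observed, tolerance = 1e-10)
})

test_that("Moran's I sign behaves as expected on structured grids", {
  chk <- density_grid_from_matrix(outer(1:8, 1:8,
                                        function(r, c) (r + c) %% 2 * 100))
  expect_lt(global_morans_i(chk), 0)       # checkerboard disperses
  grad <- density_grid_from_matrix(outer(1:8, 1:8, function(r, c) 10 * c))
  expect_gt(global_morans_i(grad), 0.5)    # smooth gradient clusters
  cst <- density_grid_from_matrix(matrix(5, 4, 4))
  expect_error(global_morans_i(cst), "zero variance")
  expect_error(local_morans_i(cst), "zero variance")
})

test_that("global Moran's I is affine invariant and the permutation-null
           mean is -1/(n-1)", {
  g <- random_grid(6, 6, seed = 3)
  w <- knn_weights(g, 4)
  i0 <- global_morans_i(g, w)
  aff <- density_grid_from_matrix(3.7 * g$sd - 120)
  expect_equal(global_morans_i(aff, w), i0, tolerance = 1e-12)
  ## permutation null
  v <- g$sd[cbind(w$cell_rc[, "row"], w$cell_rc[, "col"])]
  set.seed(99)
  perms <- replicate(2000, {
    gp <- density_grid_from_matrix(matrix(sample(v), 6, 6))
    global_morans_i(gp, w)
  })
  expected <- -1 / (w$n - 1)
  mcse <- sd(perms) / sqrt(length(perms))
  expect_lt(abs(mean(perms) - expected), 3 * mcse)
})

test_that("local Moran's I flags outliers and zero-centred cells", {
  m <- matrix(50, 5, 5); m[3, 3] <- 150      # single high cell
  g <- density_grid_from_matrix(m)
  w <- knn_weights(g, 4)
  li <- local_morans_i(g, w)
  expect_lt(li[3, 3], 0)                     # local outlier
  ## a cell exactly at the grid mean contributes zero: centre of 1..9
  g2 <- density_grid_from_matrix(matrix(1:9, 3, 3))
  li2 <- local_morans_i(g2, knn_weights(g2, 4))
  expect_equal(li2[2, 2], 0, tolerance = 1e-12)
  ## standardized variant scales by m2 only
  w2 <- knn_weights(g2, 4)
  raw <- local_morans_i(g2, w2)
  std <- local_morans_i(g2, w2, standardized = TRUE)
  vv <- g2$sd[cbind(w2$cell_rc[, "row"], w2$cell_rc[, "col"])]
  m2 <- sum((vv - mean(vv))^2) / w2$n
  expect_equal(std, raw / m2, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("relative global deviation matches hand arithmetic and is scale
           invariant", {
  g <- density_grid_from_matrix(matrix(c(1, 3), 1, 2))
  d <- relative_global_deviation(g)
  expect_equal(d$sd_bar, 2)
  expect_equal(as.vector(d$d_rel), c(0.5, 0.5))
  expect_equal(d$mean_d_rel, 0.5)
  ## uniform grid: no heterogeneity
  u <- relative_global_deviation(density_grid_from_matrix(matrix(60, 3, 3)))
  expect_true(all(u$d_rel == 0))
  expect_identical(u$mean_d_rel, 0)
  ## positive rescaling leaves d_rel unchanged
  g2 <- random_grid(4, 4, seed = 5)
  a <- relative_global_deviation(g2)
  b <- relative_global_deviation(density_grid_from_matrix(7.3 * g2$sd))
  expect_equal(a$d_rel, b$d_rel, tolerance = 1e-12)
  expect_equal(a$mean_d_rel, b$mean_d_rel, tolerance = 1e-12)
  expect_error(relative_global_deviation(
    density_grid_from_matrix(matrix(0, 2, 2))), "mean density")
})

test_that("coefficient of variation is 100 sd/mean and scale invariant", {
  g <- density_grid_from_matrix(matrix(c(50, 150), 1, 2))
  expect_equal(coefficient_of_variation(g), 100 * sd(c(50, 150)) / 100)
  expect_equal(coefficient_of_variation(g), 70.71068, tolerance = 1e-6)
  u <- density_grid_from_matrix(matrix(42, 2, 2))
  expect_equal(coefficient_of_variation(u), 0)
  g2 <- random_grid(4, 4, seed = 6)
  expect_equal(coefficient_of_variation(g2),
               coefficient_of_variation(
                 density_grid_from_matrix(3 * g2$sd)),
               tolerance = 1e-12)
})

test_that("replicate aggregation takes cellwise medians with the
           majority-validity rule", {
  a <- matrix(1, 3, 3)
  expect_equal(aggregate_replicates(list(a, a, a)), a)
  outlier <- matrix(100, 3, 3)
  expect_equal(aggregate_replicates(list(a, a, outlier)), a)
  ## different widths crop to the intersection
  wide <- cbind(a, 9)
  expect_identical(dim(aggregate_replicates(list(a, wide))), c(3L, 3L))
  ## alignment at the top-left valid anchor
  shifted <- rbind(NA, cbind(NA, a))
  expect_equal(aggregate_replicates(list(a, shifted)), a)
  ## validity in at least half of replicates
  holey <- a; holey[2, 2] <- NA
  m2 <- aggregate_replicates(list(holey, holey, a))
  expect_true(is.na(m2[2, 2]))
  m3 <- aggregate_replicates(list(holey, a, a))
  expect_false(is.na(m3[2, 2]))
})
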