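#' k-nearest-neighbour spatial weights over valid grid cells
#'
#' Binary, directed k-nearest-neighbour weights between the centres of the
#' valid cells of a density grid: `w_ij = 1` when cell j is one of the k
#' cells nearest to cell i (Euclidean distance between cell centres), and
#' 0 otherwise.  Weights are not row-standardized; the total weight is
#' `W = n * k`.  Distance ties are broken deterministically by row-major
#' cell index.
#'
#' @param grid a `density_grid`.
#' @param k number of neighbours per cell (default 4).
#' @return object of class `spatial_weights`: list with `n`, `k`,
#'   `neighbors` (n x k matrix of valid-cell indices), `W`, `cell_rc`
#'   (n x 2 matrix of grid row/column of each valid cell), and
#'   `cell_index` (row-major index of each valid cell).
#' @export
knn_weights <- function(grid, k = 4L) {
  stopifnot(inherits(grid, "density_grid"))
  k <- as.integer(k)
  idx <- which(t(grid$valid))          # row-major enumeration of valid cells
  nc <- ncol(grid$valid)
  rows <- (idx - 1L) %/% nc + 1L
  cols <- (idx - 1L) %% nc + 1L
  n <- length(idx)
  if (n <= k) stop("need more than k valid cells for k-NN weights")
  cx <- (cols - 0.5) * grid$cell_size_mm
  cy <- (rows - 0.5) * grid$cell_size_mm
  nb <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d2 <- (cx - cx[i])^2 + (cy - cy[i])^2
    d2[i] <- Inf                        # no self-neighbours
    ord <- order(d2, idx)               # ties resolved by row-major index
    nb[i, ] <- ord[seq_len(k)]
  }
  structure(list(n = n, k = k, neighbors = nb, W = n * k,
                 cell_rc = cbind(row = rows, col = cols),
                 cell_index = idx),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> %d cells, k = %d, W = %d\n", x$n, x$k, x$W))
  invisible(x)
}

#' Relative global deviation of stomatal density
#'
#' Per-cell heterogeneity relative to the group mean: the absolute
#' deviation `D_rc = |SD_rc - mean(SD)|` of each valid cell from the mean
#' density over all valid cells, and its unitless normalisation
#' `D_rc / mean(SD)`.  The signed deviation map is retained for
#' diagnostics.  Also reports the coefficient of variation.
#'
#' @param grid a `density_grid` with positive mean density.
#' @return object of class `deviation_maps`: list with matrices `d_abs`,
#'   `d_rel`, `d_signed` (NA where invalid) and scalars `sd_bar`,
#'   `mean_d_rel`, `cv_percent`.
#' @export
relative_global_deviation <- function(grid) {
  v <- valid_sd(grid)
  if (!length(v)) stop("no valid cells")
  sd_bar <- mean(v)
  if (sd_bar <= 0) stop("mean density is zero; relative deviation undefined")
  signed <- grid$sd - sd_bar
  signed[!grid$valid] <- NA_real_
  d_abs <- abs(signed)
  structure(list(d_abs = d_abs, d_rel = d_abs / sd_bar, d_signed = signed,
                 sd_bar = sd_bar,
                 mean_d_rel = mean(d_abs[grid$valid]) / sd_bar,
                 cv_percent = coefficient_of_variation(grid)),
            class = "deviation_maps")
}

#' Coefficient of variation of cell densities
#'
#' `100 * sample standard deviation / mean` over the valid cells.
#'
#' @param grid a `density_grid` (or numeric vector of densities).
#' @return percent CV.
#' @export
coefficient_of_variation <- function(grid) {
  v <- if (inherits(grid, "density_grid")) valid_sd(grid) else grid
  v <- v[is.finite(v)]
  if (length(v) < 2L) stop("need at least two valid cells")
  m <- mean(v)
  if (m <= 0) stop("mean density is zero; CV undefined")
  100 * stats::sd(v) / m
}

moran_z <- function(grid, weights) {
  stopifnot(inherits(grid, "density_grid"),
            inherits(weights, "spatial_weights"))
  v <- grid$sd[cbind(weights$cell_rc[, "row"], weights$cell_rc[, "col"])]
  z <- v - mean(v)
  if (sum(z^2) == 0)
    stop("zero variance across valid cells; Moran's I undefined")
  z
}

#' Global Moran's I over k-NN weights
#'
#' The classical global spatial autocorrelation statistic
#' `I = (n / W) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
#' `z_i = SD_i - mean(SD)`, computed over the valid cells with binary
#' directed k-NN weights.  Positive values indicate clustering of similar
#' densities, negative values dispersion, values near zero spatial
#' randomness.
#'
#' @param grid a `density_grid`.
#' @param weights a [knn_weights()] object for the same grid; computed on
#'   the fly when omitted.
#' @return scalar Moran's I.
#' @export
global_morans_i <- function(grid, weights = knn_weights(grid)) {
  z <- moran_z(grid, weights)
  lag <- rowSums(matrix(z[weights$neighbors], weights$n, weights$k))
  (weights$n / weights$W) * sum(z * lag) / sum(z^2)
}

#' Local Moran's I per grid cell
#'
#' The local decomposition `I_i = z_i * sum_j w_ij z_j` (raw product form;
#' set `standardized = TRUE` to divide by `m2 = sum(z^2) / n` for the
#' conventional LISA scaling).  Positive values mark cells surrounded by
#' similar densities, negative values local outliers.  The raw form
#' satisfies `global I = (n / W) * sum_i I_i / sum_i z_i^2` exactly.
#'
#' @inheritParams global_morans_i
#' @param standardized divide by the variance term `m2` (default `FALSE`).
#' @return matrix of `I_i` (NA where invalid), with attribute
#'   `mean_local_i`.
#' @export
local_morans_i <- function(grid, weights = knn_weights(grid),
                           standardized = FALSE) {
  z <- moran_z(grid, weights)
  lag <- rowSums(matrix(z[weights$neighbors], weights$n, weights$k))
  li <- z * lag
  if (standardized) li <- li / (sum(z^2) / weights$n)
  out <- matrix(NA_real_, nrow(grid$sd), ncol(grid$sd))
  out[cbind(weights$cell_rc[, "row"], weights$cell_rc[, "col"])] <- li
  attr(out, "mean_local_i") <- mean(li)
  out
}

#' Aggregate replicate maps by cellwise medians
#'
#' Aligns replicate matrices at their top-left valid anchor (the first
#' row and column containing any valid cell), crops them to the common
#' intersection shape, and takes the cellwise median across replicates,
#' ignoring invalid (`NA`) cells.  A cell is valid in the output when it
#' is valid in at least half of the replicates.
#'
#' @param maps list of numeric matrices with `NA` marking invalid cells.
#' @return numeric matrix of medians (`NA` where too few replicates are
#'   valid).
#' @export
aggregate_replicates <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 1L,
            all(vapply(maps, is.matrix, logical(1))))
  anchor_crop <- function(m) {
    ok <- is.finite(m)
    if (!any(ok)) stop("replicate map has no valid cells")
    r0 <- which(rowSums(ok) > 0)[1L]
    c0 <- which(colSums(ok) > 0)[1L]
    m[r0:nrow(m), c0:ncol(m), drop = FALSE]
  }
  shifted <- lapply(maps, anchor_crop)
  nr <- min(vapply(shifted, nrow, integer(1)))
  nc <- min(vapply(shifted, ncol, integer(1)))
  if (nr < 1L || nc < 1L) stop("empty intersection of replicate maps")
  arr <- vapply(shifted, function(m) m[seq_len(nr), seq_len(nc), drop = FALSE],
                matrix(0, nr, nc))
  arr <- array(arr, dim = c(nr, nc, length(maps)))
  med <- apply(arr, c(1, 2), function(v) {
    ok <- is.finite(v)
    if (sum(ok) * 2 >= length(v)) stats::median(v[ok]) else NA_real_
  })
  med
}
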