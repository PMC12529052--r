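#' Grid stomatal density on 1 mm^2 cells
#'
#' Divides the imaged extent into square cells (half-open intervals
#' `[i*cell, (i+1)*cell)` anchored at the image origin), counts detections
#' by centroid-in-cell, and computes each cell's available area as the
#' cell area minus excluded and out-of-extent area.  Cells with less than
#' `min_available_frac` of their area available are flagged invalid: their
#' density is undefined (`NA`), not zero.
#'
#' @param stomata a `stoma_set` from [detect_stomata()], or any data frame
#'   with `centroid_x_um` / `centroid_y_um` columns.
#' @param mask optional [exclusion_mask()]; its raster also defines the
#'   image extent.
#' @param extent_um numeric `c(width_um, height_um)`; required when no
#'   mask is given.
#' @param pixel_size_um calibration; taken from `stomata` or `mask` when
#'   available.
#' @param cell_size_mm cell edge length (default 1 mm).
#' @param min_available_frac validity cutoff on the available fraction of
#'   a cell (default 0.5).
#' @param meta optional named list of group labels (genotype, surface,
#'   position, replicate) stored with the grid.
#' @return object of class `density_grid`: list with matrices `sd`
#'   (stomata per mm^2, `NA` where invalid), `counts`,
#'   `available_area_mm2`, `valid`, plus `cell_size_mm` and `meta`.
#' @export
grid_density <- function(stomata, mask = NULL, extent_um = NULL,
                         pixel_size_um = NULL, cell_size_mm = 1,
                         min_available_frac = 0.5, meta = list()) {
  if (cell_size_mm <= 0) stop("'cell_size_mm' must be positive")
  if (is.null(pixel_size_um))
    pixel_size_um <- attr(stomata, "pixel_size_um")
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "exclusion_mask"))
    if (is.null(pixel_size_um)) pixel_size_um <- mask$pixel_size_um
    extent_um <- c(ncol(mask$mask), nrow(mask$mask)) * mask$pixel_size_um
  }
  if (is.null(extent_um))
    stop("supply either 'mask' or 'extent_um'")
  if (any(extent_um < cell_size_mm * 1000))
    stop("extent smaller than one grid cell")
  cell_um <- cell_size_mm * 1000
  ncell_x <- ceiling(extent_um[1] / cell_um)
  ncell_y <- ceiling(extent_um[2] / cell_um)

  counts <- matrix(0L, ncell_y, ncell_x)
  x <- stomata$centroid_x_um
  y <- stomata$centroid_y_um
  inside <- x >= 0 & x < extent_um[1] & y >= 0 & y < extent_um[2]
  if (any(!inside)) {
    warning(sum(!inside), " detection(s) outside the extent dropped")
    x <- x[inside]; y <- y[inside]
  }
  if (length(x)) {
    ix <- floor(x / cell_um) + 1L
    iy <- floor(y / cell_um) + 1L
    tab <- table(factor(iy, levels = seq_len(ncell_y)),
                 factor(ix, levels = seq_len(ncell_x)))
    counts <- matrix(as.integer(tab), ncell_y, ncell_x)
  }

  if (!is.null(mask)) {
    avail <- cell_available_area(mask$mask, mask$pixel_size_um, cell_size_mm)
    ## pad in case the raster does not reach the last partial cell
    if (nrow(avail) < ncell_y)
      avail <- rbind(avail, matrix(0, ncell_y - nrow(avail), ncol(avail)))
    if (ncol(avail) < ncell_x)
      avail <- cbind(avail, matrix(0, nrow(avail), ncell_x - ncol(avail)))
  } else {
    ## analytic cell-extent intersection (no excluded pixels)
    wx <- pmin(seq_len(ncell_x) * cell_um, extent_um[1]) -
      (seq_len(ncell_x) - 1) * cell_um
    wy <- pmin(seq_len(ncell_y) * cell_um, extent_um[2]) -
      (seq_len(ncell_y) - 1) * cell_um
    avail <- outer(wy, wx) / 1e6
  }
  valid <- avail >= min_available_frac * cell_size_mm^2
  sd <- counts / avail
  sd[!valid] <- NA_real_
  structure(list(sd = sd, counts = counts, available_area_mm2 = avail,
                 valid = valid, cell_size_mm = cell_size_mm, meta = meta),
            class = "density_grid")
}

#' Construct a density grid from a density matrix
#'
#' Wraps a ready-made matrix of stomatal densities (e.g. read from a
#' deposited gridded dataset) as a `density_grid`; `NA` entries mark
#' invalid cells.  Counts and available areas are unknown (`NA`).
#'
#' @param sd numeric matrix of densities (stomata per mm^2).
#' @param cell_size_mm cell edge length.
#' @param meta named list of group labels.
#' @return a `density_grid`.
#' @export
density_grid_from_matrix <- function(sd, cell_size_mm = 1, meta = list()) {
  stopifnot(is.matrix(sd), is.numeric(sd))
  structure(list(sd = sd,
                 counts = matrix(NA_real_, nrow(sd), ncol(sd)),
                 available_area_mm2 = matrix(NA_real_, nrow(sd), ncol(sd)),
                 valid = !is.na(sd),
                 cell_size_mm = cell_size_mm, meta = meta),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d cells of %g mm, %d valid; mean SD %.1f\n",
              nrow(x$sd), ncol(x$sd), x$cell_size_mm, sum(x$valid),
              mean(x$sd[x$valid])))
  invisible(x)
}

valid_sd <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  grid$sd[grid$valid]
}

#' Map densities to heatmap colours
#'
#' Spectral (rainbow) colour-coding with fixed scale bounds: `scale[1]`
#' maps to blue and `scale[2]` to red; values outside are clamped.
#'
#' @param values numeric vector or matrix of densities; `NA` allowed.
#' @param scale length-2 numeric bounds, default `c(0, 150)`.
#' @param na_color colour for invalid cells.
#' @return character vector/matrix of hex colours.
#' @export
density_colors <- function(values, scale = c(0, 150), na_color = "#BFBFBF") {
  stopifnot(length(scale) == 2L, scale[1] < scale[2])
  pal <- rev(grDevices::hcl.colors(256L, "Spectral"))  # blue -> red
  ramp <- grDevices::colorRamp(pal)
  v <- (pmin(pmax(values, scale[1]), scale[2]) - scale[1]) /
    (scale[2] - scale[1])
  out <- rep(na_color, length(values))
  fin <- is.finite(v)
  if (any(fin)) {
    m <- ramp(v[fin])
    out[fin] <- grDevices::rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255)
  }
  if (is.matrix(values)) out <- matrix(out, nrow(values), ncol(values))
  out
}

#' Render a density grid as an annotated heatmap
#'
#' Draws the grid with a fixed spectral colour scale (blue = `scale[1]`,
#' red = `scale[2]`), invalid cells in neutral grey, and the
#' integer-rounded density printed in the top-left corner of each cell.
#'
#' @param grid a `density_grid`.
#' @param path optional PNG output path; when `NULL` draws on the current
#'   device.
#' @param scale fixed colour bounds, default `c(0, 150)`; ignored when
#'   `autoscale` is `TRUE`.
#' @param autoscale rescale colours to the grid's own range.
#' @param annotate print per-cell integer densities.
#' @param px_per_cell PNG resolution per grid cell.
#' @return invisibly, a list with the colour matrix and the annotation
#'   values.
#' @export
render_heatmap <- function(grid, path = NULL, scale = c(0, 150),
                           autoscale = FALSE, annotate = TRUE,
                           px_per_cell = 40) {
  stopifnot(inherits(grid, "density_grid"))
  if (autoscale) {
    rng <- range(grid$sd, na.rm = TRUE)
    if (diff(rng) <= 0) rng <- rng + c(0, 1)
    scale <- rng
  }
  cols <- density_colors(grid$sd, scale)
  values <- round(grid$sd)
  nr <- nrow(grid$sd); nc <- ncol(grid$sd)
  draw <- function() {
    op <- graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
    on.exit(graphics::par(op))
    plot(NA, xlim = c(0, nc), ylim = c(nr, 0), asp = 1, axes = FALSE,
         xlab = "", ylab = "", xaxs = "i", yaxs = "i")
    xs <- rep(seq_len(nc) - 1L, each = nr)
    ys <- rep(seq_len(nr) - 1L, times = nc)
    graphics::rect(xs, ys + 1, xs + 1, ys, col = cols, border = "white",
                   lwd = 0.3)
    if (annotate) {
      lab <- ifelse(is.na(values), "", as.character(values))
      graphics::text(xs + 0.05, ys + 0.25, lab, adj = c(0, 0.5),
                     cex = 0.5, col = "black")
    }
  }
  if (!is.null(path)) {
    grDevices::png(path, width = nc * px_per_cell, height = nr * px_per_cell)
    draw()
    grDevices::dev.off()
  } else draw()
  invisible(list(colors = cols, values = values, scale = scale))
}

#' Write / read a density grid as a CSV matrix
#'
#' The density matrix is written as a plain rectangular CSV with empty
#' fields marking invalid cells; cell size and group labels go to a
#' sidecar JSON file next to it (`<path>.json`).  The round trip is
#' lossless for `sd` and `valid`; per-cell counts and available areas are
#' not part of the exchange format.
#'
#' @param grid a `density_grid`.
#' @param path CSV path.
#' @return `path` invisibly; `read_grid_csv` returns a `density_grid`.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  utils::write.table(grid$sd, path, sep = ",", na = "", row.names = FALSE,
                     col.names = FALSE)
  meta <- c(list(cell_size_mm = grid$cell_size_mm), grid$meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (!length(lines)) stop("empty grid file: ", path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  ## trailing empty fields survive by padding to the declared width
  width <- length(strsplit(paste0(lines[1], " "), ",", fixed = TRUE)[[1]])
  parse_row <- function(i) {
    f <- strsplit(paste0(lines[i], " "), ",", fixed = TRUE)[[1]]
    f <- trimws(f)
    if (length(f) != width)
      stop(sprintf("ragged grid file: row %d has %d fields, expected %d",
                   i, length(f), width))
    v <- suppressWarnings(as.numeric(f))
    bad <- is.na(v) & f != ""
    if (any(bad))
      stop(sprintf("non-numeric value '%s' in row %d", f[bad][1], i))
    v
  }
  sd <- do.call(rbind, lapply(seq_along(lines), parse_row))
  meta_path <- paste0(path, ".json")
  meta <- list()
  cell <- 1
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$cell_size_mm)) {
      cell <- meta$cell_size_mm
      meta$cell_size_mm <- NULL
    }
  }
  density_grid_from_matrix(sd, cell_size_mm = cell, meta = meta)
}
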