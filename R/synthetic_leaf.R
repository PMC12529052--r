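#' Specification of a synthetic autofluorescence leaf image
#'
#' Describes a synthetic chlorophyll-autofluorescence micrograph of a grass
#' leaf: bright mesophyll background with multiplicative speckle, dark
#' elliptical stomata arranged in parallel longitudinal files, dark
#' longitudinal vein stripes and a dark border frame (regions that cannot
#' bear stomata), and a linear base-to-tip gradient in stomatal density.
#' The leaf axis runs along x: column 0 is the leaf base, the last column
#' the tip.
#'
#' Stomata are placed file by file as a hard-core renewal process: along a
#' file, successive centres are separated by
#' `stoma_major_um + min_gap_um + Exp(rate)`, with the exponential rate
#' chosen so that the local mean spacing matches the requested density at
#' that position.  `min_gap_um` is the guaranteed edge-to-edge clearance
#' between neighbouring stomata and defaults to one stoma length, so
#' centres are never closer than twice `stoma_major_um`.
#'
#' @param width_mm,height_mm leaf extent in millimetres.
#' @param pixel_size_um calibration, micrometres per pixel side.
#' @param base_density_mm2,tip_density_mm2 stomatal density (stomata per
#'   mm^2 of available area) at the base and tip edges; interpolated
#'   linearly in between.
#' @param file_spacing_um distance between stomatal files (rows).
#' @param stoma_major_um,stoma_minor_um full ellipse axes of one stoma.
#' @param stoma_intensity_frac intensity inside stomata, veins and border
#'   as a fraction of the background intensity (dark objects, in `[0, 1)`).
#' @param vein_count number of longitudinal veins, evenly spaced in y.
#' @param vein_width_um width of each vein stripe.
#' @param border_um width of the dark border frame around the image.
#' @param noise_sd_frac standard deviation of the multiplicative Gaussian
#'   speckle, as a fraction of the local intensity.
#' @param blur_sigma_px Gaussian blur applied after speckle (pixels), to
#'   mimic correlated mesophyll texture.
#' @param background_frac mean background intensity as a fraction of the
#'   bit-depth range.
#' @param min_gap_um minimum edge-to-edge gap between stomata in a file;
#'   defaults to `stoma_major_um`.
#' @param clear_zone_um stomata-free clearance between a stoma edge and
#'   any vein or border (the costal zone of a grass leaf), default 25 um.
#' @param bit_depth 8 or 16.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @param detectable if `TRUE` (default), require the stoma ellipse area
#'   pi * a/2 * b/2 to lie in the detectable range [800, 4000] um^2.
#' @return an object of class `synthetic_leaf_spec`.
#' @seealso [generate_leaf_image()], [expected_density_field()]
#' @export
synthetic_leaf_spec <- function(width_mm = 4, height_mm = 4,
                                pixel_size_um = 1.11,
                                base_density_mm2 = 60,
                                tip_density_mm2 = 90,
                                file_spacing_um = 64,
                                stoma_major_um = 60,
                                stoma_minor_um = 24,
                                stoma_intensity_frac = 0.25,
                                vein_count = 3,
                                vein_width_um = 120,
                                border_um = 150,
                                noise_sd_frac = 0.15,
                                blur_sigma_px = 1.5,
                                background_frac = 0.45,
                                min_gap_um = stoma_major_um,
                                clear_zone_um = 25,
                                bit_depth = 16L,
                                seed = 1L,
                                detectable = TRUE) {
  spec <- list(width_mm = width_mm, height_mm = height_mm,
               pixel_size_um = pixel_size_um,
               base_density_mm2 = base_density_mm2,
               tip_density_mm2 = tip_density_mm2,
               file_spacing_um = file_spacing_um,
               stoma_major_um = stoma_major_um,
               stoma_minor_um = stoma_minor_um,
               stoma_intensity_frac = stoma_intensity_frac,
               vein_count = as.integer(vein_count),
               vein_width_um = vein_width_um,
               border_um = border_um,
               noise_sd_frac = noise_sd_frac,
               blur_sigma_px = blur_sigma_px,
               background_frac = background_frac,
               min_gap_um = min_gap_um,
               clear_zone_um = clear_zone_um,
               bit_depth = as.integer(bit_depth),
               seed = as.integer(seed),
               detectable = isTRUE(detectable))
  class(spec) <- "synthetic_leaf_spec"
  validate_leaf_spec(spec)
  spec
}

validate_leaf_spec <- function(spec) {
  with(spec, {
    if (width_mm <= 0 || height_mm <= 0 || pixel_size_um <= 0)
      stop("width_mm, height_mm and pixel_size_um must be positive")
    if (base_density_mm2 < 0 || tip_density_mm2 < 0)
      stop("densities must be non-negative")
    if (stoma_intensity_frac < 0 || stoma_intensity_frac >= 1)
      stop("stoma_intensity_frac must lie in [0, 1)")
    if (stoma_major_um <= 0 || stoma_minor_um <= 0 ||
        stoma_minor_um > stoma_major_um)
      stop("stoma axes must be positive with minor <= major")
    if (stoma_major_um >= width_mm * 1000 || stoma_minor_um >= height_mm * 1000)
      stop("degenerate geometry: stoma larger than the image")
    if (file_spacing_um <= stoma_minor_um)
      stop("degenerate geometry: file_spacing_um must exceed stoma_minor_um")
    if (noise_sd_frac < 0) stop("noise_sd_frac must be non-negative")
    if (vein_count < 0) stop("vein_count must be non-negative")
    if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
    area <- pi * (stoma_major_um / 2) * (stoma_minor_um / 2)
    if (detectable && (area < 800 || area > 4000))
      stop(sprintf(paste0("stoma ellipse area %.0f um^2 outside the ",
                          "detectable range [800, 4000] um^2"), area))
  })
  invisible(spec)
}

## derived integer seed, kept below 2^31 - 1
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %%
               2147483629)
}

## structural (vein + border) exclusion raster and vein bands in micrometres
leaf_structure <- function(spec) {
  px <- spec$pixel_size_um
  nc <- ceiling(spec$width_mm * 1000 / px)
  nr <- ceiling(spec$height_mm * 1000 / px)
  W_um <- nc * px
  H_um <- nr * px
  ## the structure is separable: a pixel is excluded iff its row is a
  ## border/vein row or its column is a border column
  row_bad <- rep(FALSE, nr)
  col_bad <- rep(FALSE, nc)
  bw <- round(spec$border_um / px)
  if (bw > 0) {
    row_bad[c(seq_len(bw), nr - seq_len(bw) + 1L)] <- TRUE
    col_bad[c(seq_len(bw), nc - seq_len(bw) + 1L)] <- TRUE
  }
  veins <- NULL
  if (spec$vein_count > 0) {
    vy <- (seq_len(spec$vein_count) - 0.5) / spec$vein_count * H_um
    veins <- cbind(lo = vy - spec$vein_width_um / 2,
                   hi = vy + spec$vein_width_um / 2)
    for (i in seq_len(nrow(veins))) {
      rows <- max(1L, ceiling(veins[i, "lo"] / px)):
        min(nr, ceiling(veins[i, "hi"] / px))
      row_bad[rows] <- TRUE
    }
  }
  excl <- outer(row_bad, col_bad, "|")
  list(nr = nr, nc = nc, W_um = W_um, H_um = H_um, bw = bw,
       excl = excl, veins = veins, row_bad = row_bad, col_bad = col_bad,
       available_mm2 = sum(!excl) * px^2 / 1e6)
}

## y positions of stomatal files admissible for stoma centres: the full
## ellipse plus the costal clear zone must stay off every vein and border
admissible_rows <- function(spec, geom, offset_um) {
  b <- spec$stoma_minor_um / 2 + spec$clear_zone_um
  px <- spec$pixel_size_um
  ys <- seq(offset_um, geom$H_um, by = spec$file_spacing_um)
  keep <- ys - b > geom$bw * px & ys + b < geom$H_um - geom$bw * px
  if (!is.null(geom$veins)) {
    for (i in seq_len(nrow(geom$veins)))
      keep <- keep & (ys + b <= geom$veins[i, "lo"] |
                        ys - b >= geom$veins[i, "hi"])
  }
  ys[keep]
}

## available/admissible length ratios per 1 mm cell column (fx) and cell
## row (gy).  "Available" counts non-excluded pixel centres; "admissible"
## is the continuous measure of positions a stoma centre may occupy
## (inside [x0, x1] in x; outside every clear zone in y).
placement_corrections <- function(spec, geom, x0, x1) {
  px <- spec$pixel_size_um
  cell_um <- 1000
  ncx <- ceiling(geom$W_um / cell_um)
  ncy <- ceiling(geom$H_um / cell_um)
  overlap <- function(lo, hi, a, b) pmax(0, pmin(hi, b) - pmax(lo, a))
  ## x: available pixel columns vs the admissible interval [x0, x1]
  xc <- (seq_len(geom$nc) - 0.5) * px
  jx <- pmin(floor(xc / cell_um) + 1L, ncx)
  len_x_avail <- vapply(seq_len(ncx), function(j)
    sum(!geom$col_bad[jx == j]) * px, numeric(1))
  len_x_adm <- vapply(seq_len(ncx), function(j)
    overlap(x0, x1, (j - 1) * cell_um, j * cell_um), numeric(1))
  fx <- ifelse(len_x_adm > 0, len_x_avail / len_x_adm, 0)
  ## y: available pixel rows vs admissible centre intervals (border and
  ## vein bands inflated by the half minor axis plus the clear zone)
  b2 <- spec$stoma_minor_um / 2 + spec$clear_zone_um
  yc <- (seq_len(geom$nr) - 0.5) * px
  iy <- pmin(floor(yc / cell_um) + 1L, ncy)
  len_y_avail <- vapply(seq_len(ncy), function(i)
    sum(!geom$row_bad[iy == i]) * px, numeric(1))
  blocks <- rbind(c(-Inf, geom$bw * px + b2),
                  c(geom$H_um - geom$bw * px - b2, Inf))
  if (!is.null(geom$veins))
    blocks <- rbind(blocks, cbind(geom$veins[, "lo"] - b2,
                                  geom$veins[, "hi"] + b2))
  len_y_adm <- vapply(seq_len(ncy), function(i) {
    lo <- (i - 1) * cell_um; hi <- min(i * cell_um, geom$H_um)
    blocked <- sum(vapply(seq_len(nrow(blocks)), function(k)
      overlap(lo, hi, blocks[k, 1], blocks[k, 2]), numeric(1)))
    max(0, (hi - lo) - blocked)
  }, numeric(1))
  gy <- ifelse(len_y_adm > 0, len_y_avail / len_y_adm, 0)
  list(fx = fx, gy = gy,
       cell_x = function(u) pmin(floor(u / cell_um) + 1L, ncx),
       cell_y = function(u) pmin(floor(u / cell_um) + 1L, ncy))
}

#' Generate a synthetic leaf image with ground truth
#'
#' Renders the image described by a [synthetic_leaf_spec()] and returns it
#' together with the exact centroids, areas and file indices of every
#' stoma drawn, plus the structural (vein + border) exclusion raster.
#' Identical spec and seed produce bit-identical output.
#'
#' @param spec a [synthetic_leaf_spec()].
#' @return A list of class `synthetic_leaf` with elements
#'   \describe{
#'     \item{image}{a [leaf_image].}
#'     \item{truth}{data frame with `centroid_x_um`, `centroid_y_um`,
#'       `area_um2`, `row_index` (one row per rendered stoma).}
#'     \item{exclusion}{logical matrix, `TRUE` where veins or border.}
#'     \item{available_mm2}{leaf area outside the exclusion raster, mm^2.}
#'   }
#' @examples
#' leaf <- generate_leaf_image(synthetic_leaf_spec(
#'   width_mm = 1, height_mm = 1, vein_count = 1, seed = 7))
#' nrow(leaf$truth)
#' @export
generate_leaf_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_leaf_spec"))
  validate_leaf_spec(spec)
  px <- spec$pixel_size_um
  geom <- leaf_structure(spec)
  a <- spec$stoma_major_um / 2
  b <- spec$stoma_minor_um / 2
  hard <- spec$stoma_major_um + spec$min_gap_um   # minimal centre distance

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)

  ## file rows: random phase so cell-level expectations are stationary
  set.seed(derive_seed(spec$seed, 0L))
  offset <- runif(1, 0, spec$file_spacing_um)
  rows_y <- admissible_rows(spec, geom, offset)

  ## stoma centres keep the ellipse plus clear zone off the border frame
  x0 <- geom$bw * px + a + spec$clear_zone_um
  x1 <- geom$W_um - geom$bw * px - a - spec$clear_zone_um

  truth <- data.frame(centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                      area_um2 = numeric(0), row_index = integer(0))
  dens_max <- max(spec$base_density_mm2, spec$tip_density_mm2)
  if (length(rows_y) > 0 && dens_max > 0 && x1 > x0) {
    ## per-cell intensity corrections: the linear density refers to the
    ## *available* area, while centres are restricted to the admissible
    ## (clear-zone) region; scaling the file intensity by the local
    ## available/admissible ratio on the canonical 1 mm cell grid makes
    ## the expected count of every cell equal density x available area
    cr <- placement_corrections(spec, geom, x0, x1)
    dens_at <- function(x)     # stomata per mm^2 at axial position x (um)
      spec$base_density_mm2 +
      (spec$tip_density_mm2 - spec$base_density_mm2) * x / geom$W_um
    nu_nominal <- dens_max * spec$file_spacing_um / 1e6
    if (nu_nominal > 0 && 1 / nu_nominal <= hard)
      stop("requested density too high for the hard-core spacing; ",
           "reduce density or stoma size / min_gap_um")
    ## local corrections cannot exceed the hard-core packing limit: cells
    ## whose admissible strip is much narrower than their available area
    ## (narrow slivers) saturate and come out slightly under-dense
    nu_cap <- 1 / (1.02 * hard)
    pieces <- vector("list", length(rows_y))
    for (k in seq_along(rows_y)) {
      gi <- cr$gy[cr$cell_y(rows_y[k])]
      nu_at <- function(x)     # stomata per um of file length at x
        min(nu_cap,
            dens_at(x) * spec$file_spacing_um * cr$fx[cr$cell_x(x)] * gi / 1e6)
      set.seed(derive_seed(spec$seed, k))
      xs <- numeric(0)
      if (gi > 0 && max(nu_at(x0), nu_at(x1)) > 0) {
        ## burn-in upstream of the left edge makes the process stationary
        x <- x0 - 10 / max(nu_at(x0), nu_at(x1))
        repeat {
          nu0 <- nu_at(min(max(x, x0), x1))
          if (nu0 <= 0) { x <- x + hard; if (x > x1) break else next }
          ## evaluate the intensity at the expected midpoint of the next
          ## gap so steps in the correction factors are tracked with at
          ## most half a gap of lag
          nu <- nu_at(min(max(x + 0.5 / nu0, x0), x1))
          if (nu <= 0) nu <- nu0
          gap_mean <- 1 / nu
          x <- x + hard + rexp(1, 1 / (gap_mean - hard))
          if (x > x1) break
          if (x >= x0) xs <- c(xs, x)
        }
      }
      if (length(xs))
        pieces[[k]] <- data.frame(centroid_x_um = xs,
                                  centroid_y_um = rows_y[k],
                                  area_um2 = pi * a * b,
                                  row_index = k)
    }
    pieces <- pieces[!vapply(pieces, is.null, logical(1))]
    if (length(pieces)) truth <- do.call(rbind, pieces)
  }
  rownames(truth) <- NULL

  ## render: background 1, dark structures at stoma_intensity_frac
  F <- matrix(1, geom$nr, geom$nc)
  F[geom$excl] <- spec$stoma_intensity_frac
  if (nrow(truth) > 0) {
    apx <- a / px
    bpx <- b / px
    idx <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      cx <- truth$centroid_x_um[i] / px    # 0-based pixel coordinates
      cy <- truth$centroid_y_um[i] / px
      rr <- max(1L, floor(cy - bpx)):min(geom$nr, ceiling(cy + bpx) + 1L)
      cc <- max(1L, floor(cx - apx)):min(geom$nc, ceiling(cx + apx) + 1L)
      inside <- outer((rr - 0.5 - cy)^2 / bpx^2,
                      (cc - 0.5 - cx)^2 / apx^2, "+") <= 1
      idx[[i]] <- as.numeric(rr[row(inside)[inside]]) +
        as.numeric(geom$nr) * (cc[col(inside)[inside]] - 1)
    }
    F[unlist(idx)] <- spec$stoma_intensity_frac
  }
  level <- spec$background_frac * (2^spec$bit_depth - 1)
  set.seed(derive_seed(spec$seed, 1000003L))
  img <- level * F
  if (spec$noise_sd_frac > 0)
    img <- img * (1 + spec$noise_sd_frac * matrix(rnorm(geom$nr * geom$nc),
                                                  geom$nr, geom$nc))
  if (spec$blur_sigma_px > 0) img <- separable_gaussian(img, spec$blur_sigma_px)
  img <- pmin(pmax(round(img), 0), 2^spec$bit_depth - 1)
  storage.mode(img) <- "integer"

  structure(list(image = leaf_image(img, pixel_size_um = px,
                                    bit_depth = spec$bit_depth),
                 truth = truth,
                 exclusion = geom$excl,
                 available_mm2 = geom$available_mm2,
                 spec = spec),
            class = "synthetic_leaf")
}

## separable Gaussian blur with edge replication (kernel +-3 sigma)
separable_gaussian <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  nr <- nrow(x); nc <- ncol(x)
  xp <- x[c(rep(1L, r), seq_len(nr), rep(nr, r)),
          c(rep(1L, r), seq_len(nc), rep(nc, r))]
  xp <- stats::filter(xp, k, sides = 2)        # down each column
  xp <- t(stats::filter(t(xp), k, sides = 2))  # along each row
  matrix(xp[r + seq_len(nr), r + seq_len(nc)], nr, nc)
}

#' @export
print.synthetic_leaf <- function(x, ...) {
  cat(sprintf("<synthetic_leaf> %d x %d px, %d stomata, %.2f mm^2 available\n",
              nrow(x$image), ncol(x$image), nrow(x$truth), x$available_mm2))
  invisible(x)
}

#' Expected stomatal density per 1 mm^2 grid cell
#'
#' The analytic counterpart of the generator: stomatal density (per mm^2
#' of available area) interpolated linearly from base to tip, evaluated at
#' each cell centre.  Cells without any available area are zero.  The
#' expected stoma count of a cell is this field times the cell's available
#' area.
#'
#' @param spec a [synthetic_leaf_spec()].
#' @param cell_size_mm grid cell edge length (default 1 mm).
#' @return numeric matrix (rows = y cells, columns = x cells).
#' @export
expected_density_field <- function(spec, cell_size_mm = 1) {
  stopifnot(inherits(spec, "synthetic_leaf_spec"))
  geom <- leaf_structure(spec)
  px <- spec$pixel_size_um
  ncell_x <- ceiling(geom$W_um / 1000 / cell_size_mm)
  ncell_y <- ceiling(geom$H_um / 1000 / cell_size_mm)
  xc <- (seq_len(ncell_x) - 0.5) * cell_size_mm * 1000      # cell centres, um
  dens <- spec$base_density_mm2 +
    (spec$tip_density_mm2 - spec$base_density_mm2) * pmin(xc, geom$W_um) /
    geom$W_um
  field <- matrix(rep(dens, each = ncell_y), ncell_y, ncell_x)
  avail <- cell_available_area(geom$excl, px, cell_size_mm)
  field[avail <= 0] <- 0
  field
}

## per-cell available (non-excluded) area in mm^2 from a raster mask
cell_available_area <- function(excl, pixel_size_um, cell_size_mm) {
  nr <- nrow(excl); nc <- ncol(excl)
  cs_px <- cell_size_mm * 1000 / pixel_size_um
  ri <- pmin(floor(((seq_len(nr) - 0.5)) / cs_px) + 1L,
             ceiling(nr / cs_px))
  ci <- pmin(floor(((seq_len(nc) - 0.5)) / cs_px) + 1L,
             ceiling(nc / cs_px))
  m <- rowsum(+(!excl), ri)                  # collapse rows into y cells
  m <- t(rowsum(t(m), ci))                   # collapse cols into x cells
  m * pixel_size_um^2 / 1e6
}

#' Write / read ground-truth stoma centroids as CSV
#'
#' @param truth data frame with columns `centroid_x_um`, `centroid_y_um`,
#'   `area_um2`, `row_index`.
#' @param path CSV path.
#' @return `path` invisibly; `read_ground_truth` returns the data frame.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth[, c("centroid_x_um", "centroid_y_um",
                             "area_um2", "row_index")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path)
}
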