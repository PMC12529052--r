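#' CLAHE parameters
#'
#' Parameters of contrast-limited adaptive histogram equalization as used
#' for autofluorescence leaf images: the local histogram is evaluated over
#' square blocks of `block_size` pixels with `histogram_bins` bins, the
#' intensity transfer function is clipped at a maximum slope, and mappings
#' are interpolated bilinearly between block centres (the fast variant).
#' The admissible slope range is `[slope_min, slope_max]`; the working
#' `slope` defaults to the midpoint of the default range.
#'
#' @param block_size odd block edge length in pixels (>= 3), default 127.
#' @param histogram_bins number of histogram bins (>= 2), default 256.
#' @param slope working contrast-limit slope.
#' @param slope_min,slope_max admissible slope bounds, defaults 8 and 14.
#' @return an object of class `clahe_params`.
#' @export
clahe_params <- function(block_size = 127L, histogram_bins = 256L,
                         slope = 11, slope_min = 8, slope_max = 14) {
  block_size <- as.integer(block_size)
  histogram_bins <- as.integer(histogram_bins)
  if (block_size < 3L || block_size %% 2L == 0L)
    stop("'block_size' must be odd and >= 3")
  if (histogram_bins < 2L) stop("'histogram_bins' must be >= 2")
  if (!(slope_min <= slope && slope <= slope_max))
    stop("'slope' must lie within [slope_min, slope_max]")
  structure(list(block_size = block_size, histogram_bins = histogram_bins,
                 slope = slope, slope_min = slope_min, slope_max = slope_max),
            class = "clahe_params")
}

#' Maximum-intensity projection of a z-stack
#'
#' Collapses a list of co-registered planes into their per-pixel maximum,
#' preserving calibration and bit depth.
#'
#' @param stack non-empty list of [leaf_image] planes of identical shape
#'   and calibration.
#' @return a [leaf_image].
#' @export
max_project <- function(stack) {
  if (!is.list(stack) || length(stack) == 0L)
    stop("'stack' must be a non-empty list of images")
  stopifnot(all(vapply(stack, is_leaf_image, logical(1))))
  d <- dim(stack[[1L]])
  cal <- pixel_size(stack[[1L]])
  for (p in stack) {
    if (!identical(dim(p), d)) stop("plane shape mismatch in stack")
    if (!identical(pixel_size(p), cal)) stop("plane calibration mismatch")
  }
  out <- Reduce(pmax, lapply(stack, unclass))
  as_leaf_image(matrix(out, d[1], d[2]), stack[[1L]])
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-based local histogram equalization with a clipped transfer-function
#' slope and bilinear interpolation of the mappings between tile centres.
#' The image is padded by edge replication to a whole number of tiles of
#' approximately `block_size` pixels, equalized, cropped back, and
#' re-quantized to the input bit depth, so downstream histogram thresholds
#' see the native intensity range.
#'
#' @param image a [leaf_image].
#' @param params a [clahe_params()].
#' @return a [leaf_image] of the same shape, calibration and bit depth.
#' @export
clahe_enhance <- function(image, params = clahe_params()) {
  stopifnot(is_leaf_image(image), inherits(params, "clahe_params"))
  d <- dim(image)
  if (params$block_size > min(d))
    stop("block_size larger than the image")
  scale <- 2^bit_depth(image) - 1
  if (diff(range(image)) == 0) return(image)   # no contrast to stretch
  x <- unclass(image) / scale
  attributes(x) <- list(dim = d)
  ntile <- pmax(2L, as.integer(round(d / params$block_size)))
  padded <- ntile * as.integer(ceiling(d / ntile))
  xp <- x[c(seq_len(d[1]), rep(d[1], padded[1] - d[1])),
          c(seq_len(d[2]), rep(d[2], padded[2] - d[2])), drop = FALSE]
  xe <- EBImage::clahe(xp, nx = ntile[1], ny = ntile[2],
                       bins = params$histogram_bins, limit = params$slope,
                       keep = TRUE)
  xe <- xe[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
  out <- pmin(pmax(round(xe * scale), 0), scale)
  storage.mode(out) <- "integer"
  as_leaf_image(out, image)
}

#' Median filter
#'
#' Replaces each pixel by the median of its square neighbourhood of radius
#' `size` pixels (window edge `2 * size + 1`); image borders are handled by
#' edge replication.  Computed with a constant-time sliding-window median,
#' then re-quantized to the input bit depth.
#'
#' @param image a [leaf_image].
#' @param size neighbourhood radius in pixels (>= 1), default 8.
#' @return a [leaf_image] of the same shape and calibration.
#' @export
median_smooth <- function(image, size = 8L) {
  stopifnot(is_leaf_image(image))
  size <- as.integer(size)
  if (size < 1L) stop("'size' must be >= 1")
  d <- dim(image)
  scale <- 2^bit_depth(image) - 1
  x <- unclass(image) / scale
  attributes(x) <- list(dim = d)
  ## replicate edges so the window never sees out-of-image values
  xp <- x[c(rep(1L, size), seq_len(d[1]), rep(d[1], size)),
          c(rep(1L, size), seq_len(d[2]), rep(d[2], size)), drop = FALSE]
  xm <- EBImage::medianFilter(xp, size, cacheSize = 16384L)
  xm <- xm[size + seq_len(d[1]), size + seq_len(d[2]), drop = FALSE]
  out <- pmin(pmax(round(xm * scale), 0), scale)
  storage.mode(out) <- "integer"
  as_leaf_image(out, image)
}

#' Full preprocessing stage
#'
#' Maximum-intensity projection (for stacks), CLAHE, then median filtering
#' -- the standard preparation of an autofluorescence leaf image before
#' threshold-based stomata detection.
#'
#' @param x a [leaf_image] or a list of planes to be max-projected.
#' @param params a [clahe_params()].
#' @param median_size radius of the median filter (pixels); 0 disables it.
#' @return a preprocessed [leaf_image].
#' @export
preprocess_image <- function(x, params = clahe_params(), median_size = 8L) {
  img <- if (is.list(x) && !is_leaf_image(x)) max_project(x) else x
  stopifnot(is_leaf_image(img))
  img <- clahe_enhance(img, params)
  if (median_size >= 1L) img <- median_smooth(img, median_size)
  img
}
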