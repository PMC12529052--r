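#' Calibrated single-channel image
#'
#' The basic raster all detection operates on: an integer-valued intensity
#' matrix (rows = y, increasing downwards; columns = x) together with its
#' pixel calibration in micrometres per pixel side and the acquisition bit
#' depth.
#'
#' @param pixels numeric matrix of intensities in `[0, 2^bit_depth - 1]`.
#' @param pixel_size_um length of one pixel side in micrometres (> 0).
#' @param bit_depth integer, 8 or 16.
#' @return An object of class `leaf_image`: the pixel matrix with
#'   attributes `pixel_size_um` and `bit_depth`.
#' @examples
#' img <- leaf_image(matrix(0:99, 10, 10), pixel_size_um = 1.11, bit_depth = 8)
#' dim(img)
#' @export
leaf_image <- function(pixels, pixel_size_um = 1.11, bit_depth = 16L) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || any(dim(pixels) < 1L))
    stop("'pixels' must be a non-empty numeric matrix")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be a single positive number")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("'bit_depth' must be 8 or 16")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 2^bit_depth - 1)
    stop("pixel intensities outside [0, 2^bit_depth - 1]")
  structure(pixels,
            pixel_size_um = pixel_size_um,
            bit_depth     = bit_depth,
            class         = c("leaf_image", "matrix", "array"))
}

#' @export
print.leaf_image <- function(x, ...) {
  cat(sprintf("<leaf_image> %d x %d px, %.3f um/px, %d-bit, range [%d, %d]\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um"),
              attr(x, "bit_depth"), min(x), max(x)))
  invisible(x)
}

is_leaf_image <- function(x) inherits(x, "leaf_image")

#' @rdname leaf_image
#' @param x object to query.
#' @export
pixel_size <- function(x) attr(x, "pixel_size_um")

#' @rdname leaf_image
#' @export
bit_depth <- function(x) attr(x, "bit_depth")

## rebuild a leaf_image from a plain matrix, copying calibration from `like`
as_leaf_image <- function(pixels, like) {
  leaf_image(pixels, pixel_size_um = attr(like, "pixel_size_um"),
             bit_depth = attr(like, "bit_depth"))
}

#' Read a grayscale image from TIFF or PNG
#'
#' The file is read into the native integer range of its bit depth.  Multi
#' channel files are reduced to their first channel.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param pixel_size_um calibration to attach (micrometres per pixel).
#' @param bit_depth bit depth of the stored data; `NULL` guesses 16 for TIFF
#'   and from the value range for PNG.
#' @return a [leaf_image].
#' @export
read_leaf_image <- function(path, pixel_size_um = 1.11, bit_depth = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    if (is.null(bit_depth)) bit_depth <- if (max(px) > 255) 16L else 16L
  } else if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    if (is.null(bit_depth)) bit_depth <- 8L
    px <- round(px * (2^bit_depth - 1))
  } else stop("unsupported image format: ", ext)
  leaf_image(px, pixel_size_um = pixel_size_um, bit_depth = bit_depth)
}

#' Write a grayscale image to TIFF or PNG
#'
#' @param image a [leaf_image].
#' @param path destination path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_leaf_image <- function(image, path) {
  stopifnot(is_leaf_image(image))
  scale <- 2^attr(image, "bit_depth") - 1
  norm <- unclass(image) / scale
  attributes(norm) <- list(dim = dim(image))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = attr(image, "bit_depth"))
  } else if (ext == "png") {
    png::writePNG(norm, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (255 = excluded)
#'
#' @param mask logical matrix, or an object with a `$mask` element.
#' @param path destination `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  if (is.list(mask)) mask <- mask$mask
  stopifnot(is.logical(mask), is.matrix(mask))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  png::writePNG(m, path)
  invisible(path)
}
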