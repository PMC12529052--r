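## ---- connected components and particle measurement -----------------------

## 8-connected labelling: 4-connected pass, then merge labels that touch
## diagonally (union-find via graph components)
label_particles <- function(binary) {
  stopifnot(is.matrix(binary))
  lab <- EBImage::bwlabel(binary)
  nlab <- max(lab)
  if (nlab < 2L) return(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # \ diagonal neighbours
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]    # / diagonal neighbours
  s1 <- a1 > 0 & b1 > 0 & a1 != b1
  s2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[s1], b1[s1]), cbind(a2[s2], b2[s2])))
  if (nrow(pairs) == 0L) return(matrix(as.integer(lab), nr, nc))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(pairs[, 1]), to = as.character(pairs[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(nlab))))
  memb <- igraph::components(g)$membership[as.character(seq_len(nlab))]
  out <- matrix(0L, nr, nc)
  nz <- lab > 0
  out[nz] <- as.integer(memb[lab[nz]])
  out
}

## per-label area, centroid and Crofton (2-direction) perimeter
## perimeter_px = pi/4 * (horizontal + vertical boundary transitions),
## which is unbiased for smooth convex shapes such as ellipses
particle_features <- function(labels, pixel_size_um) {
  nlab <- max(labels)
  if (nlab == 0L)
    return(data.frame(label = integer(0), area_px = numeric(0),
                      area_um2 = numeric(0), perimeter_um = numeric(0),
                      circularity = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0)))
  nr <- nrow(labels); nc <- ncol(labels)
  idx <- which(labels > 0L)
  lv <- labels[idx]
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  area_px <- tabulate(lv, nlab)
  cx <- rowsum(cc - 0.5, lv)[, 1] / area_px      # 0-based pixel centres
  cy <- rowsum(rr - 0.5, lv)[, 1] / area_px
  padded <- matrix(0L, nr + 2L, nc + 2L)
  padded[1L + seq_len(nr), 1L + seq_len(nc)] <- labels
  count_transitions <- function(a, b) {
    s <- a != b
    v <- c(a[s], b[s])
    tabulate(v[v > 0L], nlab)
  }
  nh <- count_transitions(padded[, -ncol(padded)], padded[, -1])
  nv <- count_transitions(padded[-nrow(padded), ], padded[-1, ])
  per_px <- pi / 4 * (nh + nv)
  data.frame(label = seq_len(nlab),
             area_px = area_px,
             area_um2 = area_px * pixel_size_um^2,
             perimeter_um = per_px * pixel_size_um,
             circularity = 4 * pi * area_px / per_px^2,
             centroid_x_um = cx * pixel_size_um,
             centroid_y_um = cy * pixel_size_um)
}

#' Measure and filter particles in a thresholded raster
#'
#' Labels 8-connected foreground components, measures area (pixel count
#' times pixel area), perimeter (Crofton two-direction estimator) and
#' circularity `4 * pi * area / perimeter^2`, and keeps the components
#' whose area and circularity fall within the rule's bounds.
#'
#' @param binary logical matrix (TRUE = candidate object pixels).
#' @param pixel_size_um pixel calibration in micrometres.
#' @param rule a [threshold_rule()].
#' @return data frame of detections with columns `centroid_x_um`,
#'   `centroid_y_um`, `area_um2`, `circularity`, `method`.
#' @export
find_particles <- function(binary, pixel_size_um, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  feats <- particle_features(label_particles(binary), pixel_size_um)
  keep <- feats$area_um2 >= rule$area_min_um2 &
    feats$area_um2 <= rule$area_max_um2 &
    feats$circularity >= rule$circ_min &
    feats$circularity <= rule$circ_max
  out <- feats[keep, c("centroid_x_um", "centroid_y_um",
                       "area_um2", "circularity")]
  out$method <- rep(rule$method, nrow(out))
  rownames(out) <- NULL
  out
}

## histogram an integer image into `bins` equal-width bins over its native
## range; returns counts plus the intensity upper edge of each bin
image_histogram <- function(image, bins = 256L) {
  scale <- 2^bit_depth(image)
  width <- scale / bins
  counts <- tabulate(pmin(floor(unclass(image) / width) + 1L, bins), bins)
  list(counts = counts, bin_upper = seq_len(bins) * width - 1)
}

## dark-side binary at an auto-threshold cut (stomata do not fluoresce);
## a precomputed histogram may be shared across methods
dark_binary <- function(image, method, bins = 256L, target = 0.5,
                        hist = NULL) {
  h <- if (is.null(hist)) image_histogram(image, bins) else hist
  b <- auto_threshold(h$counts, method, target = target)
  unclass(image) <= h$bin_upper[b]
}

#' Exclusion mask for veins, borders and degraded areas
#'
#' Identifies image regions that cannot bear stomata: the image is cut at
#' its Percentile threshold (dark side), the binary is cleaned by a
#' morphological opening, and 8-connected dark components larger than
#' `min_area_um2` (default 400 000 um^2) become the mask.  Smaller dark
#' components -- candidate stomata -- are never excluded.
#'
#' The opening restricts the mask to *solid* dark structures (veins,
#' borders, degraded patches).  Without it, the percentile cut -- which by
#' construction marks about half of all pixels on a structure-free image
#' -- links background pixels into sprawling filamentous clusters that
#' would spuriously exceed the area cutoff.
#'
#' @param image preprocessed [leaf_image].
#' @param min_area_um2 minimum component area to be treated as excluded.
#' @param target cumulative fraction of the percentile threshold.
#' @param opening_radius_px radius of the disc structuring element used to
#'   open the binary (pixels); 0 disables the cleaning.
#' @return object of class `exclusion_mask`: list with `mask` (logical
#'   matrix), `excluded_area_um2`, and `pixel_size_um`.
#' @export
exclusion_mask <- function(image, min_area_um2 = 400000, target = 0.5,
                           opening_radius_px = 5L) {
  stopifnot(is_leaf_image(image))
  px <- pixel_size(image)
  bin <- dark_binary(image, "percentile", target = target)
  if (opening_radius_px >= 1L) {
    brush <- EBImage::makeBrush(2L * as.integer(opening_radius_px) + 1L,
                                "disc")
    bin <- EBImage::opening(bin, brush) > 0.5
  }
  labels <- label_particles(bin)
  mask <- matrix(FALSE, nrow(image), ncol(image))
  if (max(labels) > 0L) {
    area_um2 <- tabulate(labels[labels > 0L], max(labels)) * px^2
    big <- which(area_um2 > min_area_um2)
    if (length(big)) mask <- matrix(labels %in% big, nrow(image), ncol(image))
  }
  structure(list(mask = mask,
                 excluded_area_um2 = sum(mask) * px^2,
                 pixel_size_um = px),
            class = "exclusion_mask")
}

#' @export
print.exclusion_mask <- function(x, ...) {
  cat(sprintf("<exclusion_mask> %d x %d px, %.2f mm^2 excluded\n",
              nrow(x$mask), ncol(x$mask), x$excluded_area_um2 / 1e6))
  invisible(x)
}

#' Detect stomata by multi-method auto-thresholding
#'
#' Applies each threshold rule independently to the preprocessed image
#' (keeping the dark side of the cut, since stomata do not fluoresce),
#' measures and gates the resulting particles, pools the per-rule
#' detections in the order the rules are listed, and merges detections
#' whose centroids lie within `merge_radius_um` of an already accepted
#' one (the earliest rule wins).  Detections whose centroid pixel falls
#' inside the exclusion mask are removed.
#'
#' A rule whose threshold fails (e.g. Minimum on a histogram that never
#' becomes bimodal) is skipped with a warning; the detection fails only if
#' every rule fails.
#'
#' @param image preprocessed [leaf_image].
#' @param rules non-empty list of [threshold_rule()] objects; default
#'   [threshold_rules()].
#' @param mask optional [exclusion_mask()].
#' @param merge_radius_um de-duplication radius (about half a stoma length).
#' @return data frame of class `stoma_set` with columns `centroid_x_um`,
#'   `centroid_y_um`, `area_um2`, `circularity`, `method`, and attributes
#'   `n_per_rule` (named pooled counts before merging) and `pixel_size_um`.
#' @export
detect_stomata <- function(image, rules = threshold_rules(), mask = NULL,
                           merge_radius_um = 25) {
  stopifnot(is_leaf_image(image), length(rules) > 0L)
  px <- pixel_size(image)
  per_rule <- vector("list", length(rules))
  failures <- character(0)
  h <- image_histogram(image)
  for (i in seq_along(rules)) {
    rule <- rules[[i]]
    res <- tryCatch({
      find_particles(dark_binary(image, rule$method, hist = h), px, rule)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", rule$method, res$message))
      per_rule[[i]] <- NULL
    } else per_rule[[i]] <- res
  }
  ok <- !vapply(per_rule, is.null, logical(1))
  if (!any(ok))
    stop("every threshold rule failed: ", paste(failures, collapse = "; "))
  if (length(failures))
    warning("threshold rule(s) skipped: ", paste(failures, collapse = "; "))
  pooled <- do.call(rbind, per_rule[ok])
  n_per_rule <- vapply(per_rule[ok], nrow, integer(1))
  names(n_per_rule) <- vapply(rules[ok], `[[`, character(1), "method")

  merged <- merge_detections(pooled, merge_radius_um)

  if (!is.null(mask)) {
    stopifnot(inherits(mask, "exclusion_mask"))
    if (nrow(merged) > 0L) {
      rr <- pmin(pmax(ceiling(merged$centroid_y_um / px), 1L), nrow(mask$mask))
      cc <- pmin(pmax(ceiling(merged$centroid_x_um / px), 1L), ncol(mask$mask))
      merged <- merged[!mask$mask[cbind(rr, cc)], , drop = FALSE]
    }
  }
  rownames(merged) <- NULL
  structure(merged, n_per_rule = n_per_rule, pixel_size_um = px,
            class = c("stoma_set", "data.frame"))
}

## greedy union: keep a detection unless it lies within `radius` of an
## already kept one (input order = rule priority order)
merge_detections <- function(det, radius) {
  n <- nrow(det)
  if (n <= 1L) return(det)
  keep <- logical(n)
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(n)) {
    if (length(kx) == 0L ||
        min((kx - det$centroid_x_um[i])^2 + (ky - det$centroid_y_um[i])^2) >
        radius^2) {
      keep[i] <- TRUE
      kx <- c(kx, det$centroid_x_um[i])
      ky <- c(ky, det$centroid_y_um[i])
    }
  }
  det[keep, , drop = FALSE]
}

#' Stomatal density
#'
#' Number of stomata divided by the available leaf area, i.e. the total
#' area minus the excluded (vein, border, degraded) area, in stomata per
#' mm^2.
#'
#' @param n_stomata stoma count.
#' @param total_area_um2 total imaged area in um^2.
#' @param excluded_area_um2 excluded area in um^2 (<= total).
#' @return density in stomata per mm^2.
#' @examples
#' stomatal_density(100, 2e6, 0.5e6)  # 66.67 per mm^2
#' @export
stomatal_density <- function(n_stomata, total_area_um2,
                             excluded_area_um2 = 0) {
  if (excluded_area_um2 > total_area_um2)
    stop("excluded area exceeds total area")
  avail <- total_area_um2 - excluded_area_um2
  if (avail <= 0) stop("available area is zero; density undefined")
  n_stomata / (avail / 1e6)
}

#' Write / read a detection table as CSV
#' @param detections a `stoma_set` data frame.
#' @param path CSV path.
#' @return `path` invisibly; the reader returns the data frame.
#' @export
write_detections_csv <- function(detections, path) {
  utils::write.csv(as.data.frame(detections), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) utils::read.csv(path)
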