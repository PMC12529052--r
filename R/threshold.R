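#' Automatic histogram thresholding
#'
#' Computes a single intensity cut from a histogram of per-bin pixel
#' counts, by one of four classical auto-threshold algorithms:
#' \describe{
#'   \item{`li`}{Li & Tam's iterative minimum cross-entropy fixed point.}
#'   \item{`moments`}{Tsai's moment-preserving bilevel threshold: the cut
#'     is placed at the p0-tile that preserves the first three gray-level
#'     moments.}
#'   \item{`minimum`}{Prewitt & Mendelsohn's mode method: the histogram is
#'     smoothed with a running mean of 3 until exactly two local maxima
#'     remain; the cut is the valley between them.}
#'   \item{`percentile`}{Doyle's p-tile method: the smallest bin at which
#'     the cumulative fraction reaches `target` (default 0.5).}
#' }
#'
#' The returned value is a bin index `b` (1-based): the dark side of the
#' cut comprises bins `1..b`.  For an image quantized into these bins,
#' pixels in those bins are "below threshold".
#'
#' @param counts numeric vector of non-negative per-bin pixel counts.
#' @param method one of `"moments"`, `"li"`, `"minimum"`, `"percentile"`.
#' @param target cumulative fraction for the percentile method.
#' @param max_smooth maximum smoothing passes for the minimum method.
#' @return integer bin index in `1..(length(counts) - 1)`.
#' @examples
#' h <- numeric(256); h[10] <- 500; h[200] <- 500
#' auto_threshold(h, "li")
#' @export
auto_threshold <- function(counts,
                           method = c("moments", "li", "minimum",
                                      "percentile"),
                           target = 0.5, max_smooth = 10000L) {
  method <- match.arg(method)
  if (length(counts) < 2L || any(counts < 0) || !all(is.finite(counts)))
    stop("'counts' must be a non-negative finite histogram of length >= 2")
  if (sum(counts) == 0) stop("all-zero histogram")
  if (sum(counts > 0) < 2L)
    stop("histogram needs at least two non-zero bins")
  switch(method,
         li         = threshold_li(counts),
         moments    = threshold_moments(counts),
         minimum    = threshold_minimum(counts, max_smooth),
         percentile = threshold_percentile(counts, target))
}

## Li minimum cross-entropy: iterate t <- (mu_b - mu_f)/(log mu_b - log mu_f)
## on bin centres 0.5, 1.5, ... (kept positive so logs are defined)
threshold_li <- function(counts) {
  n <- length(counts)
  centers <- seq_len(n) - 0.5
  t_cur <- sum(counts * centers) / sum(counts)   # start at the global mean
  for (iter in seq_len(1000L)) {
    lo <- centers <= t_cur
    w0 <- sum(counts[lo]);  w1 <- sum(counts[!lo])
    if (w0 == 0 || w1 == 0) break
    m0 <- sum(counts[lo] * centers[lo]) / w0
    m1 <- sum(counts[!lo] * centers[!lo]) / w1
    t_new <- (m0 - m1) / (log(m0) - log(m1))
    if (abs(t_new - t_cur) < 0.5) { t_cur <- t_new; break }
    t_cur <- t_new
  }
  b <- sum(centers <= t_cur)
  as.integer(min(max(b, 1L), n - 1L))
}

## Tsai moment preservation: solve for the fraction p0 of below-threshold
## pixels that preserves moments m1..m3, then cut at the p0-tile
threshold_moments <- function(counts) {
  n <- length(counts)
  p <- counts / sum(counts)
  g <- seq_len(n) - 1                       # gray levels 0 .. n-1
  m1 <- sum(g * p); m2 <- sum(g^2 * p); m3 <- sum(g^3 * p)
  cd <- m2 - m1^2                           # m0 = 1
  if (cd <= 0) stop("degenerate histogram for moments thresholding")
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) stop("moments thresholding failed (no real roots)")
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  p0 <- (z1 - m1) / (z1 - z0)               # fraction of the dark phase
  cum <- cumsum(p)
  b <- which(cum >= p0)[1L]                 # smallest bin reaching p0
  if (is.na(b)) b <- n - 1L
  as.integer(min(max(b, 1L), n - 1L))
}

## Prewitt & Mendelsohn mode method: smooth with a running mean of 3 until
## the histogram carries exactly two strict local maxima (interior bins
## strictly above both neighbours), then cut at the valley between them
threshold_minimum <- function(counts, max_smooth = 10000L) {
  h <- as.numeric(counts)
  n <- length(h)
  iter <- 0L
  repeat {
    peaks <- which(c(FALSE, diff(h) > 0) & c(h[-n] > h[-1], FALSE))
    if (length(peaks) == 2L) break
    h <- (h[c(1L, seq_len(n - 1L))] + h + h[c(seq_len(n - 1L) + 1L, n)]) / 3
    iter <- iter + 1L
    if (iter > max_smooth)
      stop("histogram is unimodal or does not become bimodal ",
           "under smoothing; minimum thresholding undefined")
  }
  valley_range <- peaks[1L]:peaks[2L]
  b <- valley_range[which.min(h[valley_range])]
  as.integer(min(max(b, 1L), n - 1L))
}

## Doyle p-tile: smallest bin whose cumulative fraction reaches the target
threshold_percentile <- function(counts, target = 0.5) {
  if (target <= 0 || target >= 1) stop("'target' must lie in (0, 1)")
  cum <- cumsum(counts) / sum(counts)
  b <- which(cum >= target)[1L]
  as.integer(min(max(b, 1L), length(counts) - 1L))
}

#' Threshold rule: method plus particle gates
#'
#' Bundles an auto-threshold method with the particle filters applied to
#' the resulting connected components: an area window (um^2) and a
#' circularity window (`4 * pi * area / perimeter^2`).
#'
#' @param method auto-threshold method name.
#' @param area_min_um2,area_max_um2 particle area bounds in um^2.
#' @param circ_min,circ_max circularity bounds in `[0, 1]`.
#' @return an object of class `threshold_rule`.
#' @export
threshold_rule <- function(method, area_min_um2 = 800, area_max_um2 = 4000,
                           circ_min = 0.5, circ_max = 0.9) {
  stopifnot(method %in% c("moments", "li", "minimum", "percentile"))
  if (!(area_min_um2 < area_max_um2))
    stop("area_min_um2 must be smaller than area_max_um2")
  if (!(0 <= circ_min && circ_min < circ_max && circ_max <= 1))
    stop("need 0 <= circ_min < circ_max <= 1")
  structure(list(method = method,
                 area_min_um2 = area_min_um2, area_max_um2 = area_max_um2,
                 circ_min = circ_min, circ_max = circ_max),
            class = "threshold_rule")
}

#' Default stomata detection rules
#'
#' Moments and Li thresholding with an area window of 800--4000 um^2,
#' Minimum thresholding with 800--3000 um^2, all with circularity
#' 0.5--0.9, applied in that order.
#'
#' @return list of [threshold_rule] objects.
#' @export
threshold_rules <- function() {
  list(threshold_rule("moments", 800, 4000),
       threshold_rule("li",      800, 4000),
       threshold_rule("minimum", 800, 3000))
}
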