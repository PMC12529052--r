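## Independent, deliberately literal reference implementations used to
## freeze expected values.  These stay scalar/loop-based so they share no
## code path with the package.

## Li & Tam minimum cross-entropy threshold, stepwise on bin centres
oracle_li <- function(counts) {
  n <- length(counts)
  centers <- (1:n) - 0.5
  t_cur <- sum(counts * centers) / sum(counts)
  repeat {
    s0 <- 0; w0 <- 0; s1 <- 0; w1 <- 0
    for (i in 1:n) {
      if (centers[i] <= t_cur) { s0 <- s0 + counts[i] * centers[i]
                                 w0 <- w0 + counts[i] }
      else                     { s1 <- s1 + counts[i] * centers[i]
                                 w1 <- w1 + counts[i] }
    }
    if (w0 == 0 || w1 == 0) break
    m0 <- s0 / w0; m1 <- s1 / w1
    t_new <- (m0 - m1) / (log(m0) - log(m1))
    if (abs(t_new - t_cur) < 0.5) { t_cur <- t_new; break }
    t_cur <- t_new
  }
  b <- 0
  for (i in 1:n) if (centers[i] <= t_cur) b <- i
  min(max(b, 1L), n - 1L)
}

## Tsai moment-preserving threshold, stepwise
oracle_moments <- function(counts) {
  n <- length(counts)
  total <- sum(counts)
  m1 <- 0; m2 <- 0; m3 <- 0
  for (i in 1:n) {
    g <- i - 1
    p <- counts[i] / total
    m1 <- m1 + g * p; m2 <- m2 + g^2 * p; m3 <- m3 + g^3 * p
  }
  cd <- m2 - m1^2
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  z0 <- 0.5 * (-c1 - sqrt(c1^2 - 4 * c0))
  z1 <- 0.5 * (-c1 + sqrt(c1^2 - 4 * c0))
  p0 <- (z1 - m1) / (z1 - z0)
  cum <- 0
  for (i in 1:n) {
    cum <- cum + counts[i] / total
    if (cum >= p0) return(min(max(i, 1L), n - 1L))
  }
  n - 1L
}

## Prewitt & Mendelsohn minimum: smooth until exactly two strict interior
## maxima remain, then take the first minimum of the valley between them
oracle_minimum <- function(counts) {
  h <- as.numeric(counts)
  n <- length(h)
  strict_peaks <- function(h) {
    p <- integer(0)
    for (i in 2:(n - 1))
      if (h[i] > h[i - 1] && h[i] > h[i + 1]) p <- c(p, i)
    p
  }
  it <- 0
  repeat {
    peaks <- strict_peaks(h)
    if (length(peaks) == 2) break
    h2 <- h
    for (i in 1:n) {
      lo <- if (i == 1) h[1] else h[i - 1]
      hi <- if (i == n) h[n] else h[i + 1]
      h2[i] <- (lo + h[i] + hi) / 3
    }
    h <- h2
    it <- it + 1
    if (it > 10000) stop("oracle: not bimodal")
  }
  valley <- peaks[1]
  best <- Inf
  for (i in peaks[1]:peaks[2]) if (h[i] < best) { best <- h[i]; valley <- i }
  min(max(valley, 1L), n - 1L)
}

## Doyle p-tile by explicit cumulative walk
oracle_percentile <- function(counts, target = 0.5) {
  total <- sum(counts)
  cum <- 0
  for (i in seq_along(counts)) {
    cum <- cum + counts[i]
    if (cum / total >= target) return(min(max(i, 1L), length(counts) - 1L))
  }
  length(counts) - 1L
}

## brute-force square-window median with edge replication
oracle_median_filter <- function(mat, size) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- mat
  for (r in 1:nr) for (c in 1:nc) {
    vals <- c()
    for (dr in -size:size) for (dc in -size:size) {
      rr <- min(max(r + dr, 1), nr)
      cc <- min(max(c + dc, 1), nc)
      vals <- c(vals, mat[rr, cc])
    }
    out[r, c] <- median(vals)
  }
  out
}

## nested-loop global Moran's I directly from the printed double sum
oracle_global_moran <- function(values, neighbors) {
  n <- length(values)
  zbar <- mean(values)
  W <- 0; num <- 0; den <- 0
  for (i in 1:n) {
    den <- den + (values[i] - zbar)^2
    for (j in seq_len(ncol(neighbors))) {
      W <- W + 1
      num <- num + (values[i] - zbar) * (values[neighbors[i, j]] - zbar)
    }
  }
  (n / W) * num / den
}

## nested-loop local Moran's I (raw product form)
oracle_local_moran <- function(values, neighbors) {
  n <- length(values)
  zbar <- mean(values)
  out <- numeric(n)
  for (i in 1:n) {
    s <- 0
    for (j in seq_len(ncol(neighbors)))
      s <- s + (values[neighbors[i, j]] - zbar)
    out[i] <- (values[i] - zbar) * s
  }
  out
}

## exhaustive k-NN with (distance, row-major index) ordering
oracle_knn <- function(cx, cy, idx, k) {
  n <- length(cx)
  nb <- matrix(0L, n, k)
  for (i in 1:n) {
    d <- sqrt((cx - cx[i])^2 + (cy - cy[i])^2)
    d[i] <- Inf
    ord <- order(d, idx)
    nb[i, ] <- ord[1:k]
  }
  nb
}

## Benjamini-Hochberg step-up, literal
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    i <- ord[k]
    val <- min(prev, p[i] * m / k)
    adj[i] <- val
    prev <- val
  }
  adj
}

## density grid straight from a matrix of densities (all cells valid
## unless NA)
toy_grid <- function(m) density_grid_from_matrix(m)
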