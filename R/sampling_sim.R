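#' Monte Carlo subsampling of a gridded density population
#'
#' For each requested sample size n, draws `iterations` random samples of
#' n cells without replacement from the population of valid cell
#' densities and summarises them: mean and standard deviation of the
#' sample means, mean absolute and relative error against the population
#' mean, mean standard error, and the fraction of iterations whose 95%
#' t-distribution confidence interval contains the population mean.
#'
#' At `n = 1` no t-interval exists; coverage is recorded as 0.  At
#' `n = N` every without-replacement sample reproduces the population
#' exactly, so the relative error is 0 and coverage 1.  Results are fully
#' reproducible: each sample size uses an independent sub-stream derived
#' from `seed`, so subsets of sizes give identical draws.
#'
#' @param values numeric vector of valid cell densities (the population).
#' @param sizes sample sizes to simulate; default `1:length(values)`.
#' @param iterations iterations per sample size (default 1000).
#' @param seed integer seed.
#' @param conf confidence level of the t-interval (default 0.95).
#' @return data frame of class `sampling_sim` with one row per sample
#'   size: `n`, `mean_sd_of_samples`, `sd_of_samples`, `mean_abs_error`,
#'   `mean_rel_error` (fraction), `mean_se`, `ci_coverage`; attributes
#'   `population_mean`, `population_size`, `iterations`, `seed`.
#' @export
subsample_population <- function(values, sizes = seq_along(values),
                                 iterations = 1000L, seed = 1L,
                                 conf = 0.95) {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values)))
    stop("'values' must be finite and non-empty")
  N <- length(values)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1L) || any(sizes > N))
    stop("sample sizes must lie in 1..N")
  mu <- mean(values)
  if (mu == 0) stop("population mean is zero; relative error undefined")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  rows <- lapply(sizes, function(n) {
    set.seed(derive_seed(seed, n))
    draws <- vapply(seq_len(iterations),
                    function(i) values[sample.int(N, n)], numeric(n))
    draws <- matrix(draws, nrow = n)
    means <- colMeans(draws)
    if (n > 1L) {
      sds <- sqrt((colSums(draws^2) - n * means^2) / (n - 1L))
      sds <- ifelse(sds < 0 | !is.finite(sds), 0, sds)   # guard rounding
      se <- sds / sqrt(n)
      tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1L)
      covered <- mean(means - tq * se <= mu & mu <= means + tq * se)
      mean_se <- mean(se)
    } else {
      covered <- 0
      mean_se <- NA_real_
    }
    data.frame(n = n,
               mean_sd_of_samples = mean(means),
               sd_of_samples = if (iterations > 1L) stats::sd(means)
                               else NA_real_,
               mean_abs_error = mean(abs(means - mu)),
               mean_rel_error = mean(abs(means - mu)) / abs(mu),
               mean_se = mean_se,
               ci_coverage = covered)
  })
  out <- do.call(rbind, rows)
  structure(out, population_mean = mu, population_size = N,
            iterations = as.integer(iterations), seed = as.integer(seed),
            class = c("sampling_sim", "data.frame"))
}

#' Minimum sampling requirement
#'
#' The smallest simulated sample size that simultaneously achieves at
#' most `max_rel_err` mean relative error and at least `min_coverage`
#' confidence-interval coverage of the true population mean.  Because no
#' t-interval exists for a single cell, the floor is two cells even for a
#' perfectly uniform leaf.
#'
#' @param result a [subsample_population()] result.
#' @param max_rel_err mean relative error criterion (default 0.10).
#' @param min_coverage CI coverage criterion (default 0.95).
#' @return list with `n_min` (cells; `NA` when no simulated size
#'   qualifies), `fraction` of the population (for 1 mm^2 cells this is
#'   also the area fraction), `achieved`, and the criteria used.
#' @export
min_sampling_requirement <- function(result, max_rel_err = 0.10,
                                     min_coverage = 0.95) {
  stopifnot(inherits(result, "sampling_sim"))
  ok <- result$mean_rel_error <= max_rel_err &
    result$ci_coverage >= min_coverage
  N <- attr(result, "population_size")
  if (!any(ok))
    return(list(n_min = NA_integer_, fraction = NA_real_, achieved = FALSE,
                max_rel_err = max_rel_err, min_coverage = min_coverage))
  n_min <- result$n[which(ok)[1L]]
  list(n_min = as.integer(n_min), fraction = n_min / N, achieved = TRUE,
       max_rel_err = max_rel_err, min_coverage = min_coverage)
}

#' Structure-function correlations under sampling regimes
#'
#' Relates gas-exchange observations (stomatal conductance) to stomatal
#' density estimated from subsamples of each paired density grid, under
#' sampling regimes of increasing area: for each regime and each paired
#' observation, a seeded random number of cells inside the regime's range
#' is drawn without replacement from the grid's valid cells and averaged,
#' and the gas-exchange variable is regressed on the sampled densities by
#' ordinary least squares.  P-values of the slope are Benjamini-Hochberg
#' adjusted across all regressions in the call.
#'
#' @param grids list of `density_grid` objects, one per observation.
#' @param gsw numeric vector of stomatal conductance (or any paired
#'   physiological variable), same length as `grids`.
#' @param regimes named list of `c(min_cells, max_cells)` ranges; the
#'   default mirrors small (1--3 cells), medium (10--30 cells) and large
#'   (50+ cells) sampling areas.
#' @param seed integer seed.
#' @return data frame with one row per regime: `regime`, `n_pairs`,
#'   `mean_cells`, `slope`, `intercept`, `r_squared`, `p_value`, `p_adj`.
#' @export
regime_correlation <- function(grids, gsw,
                               regimes = list(small = c(1, 3),
                                              medium = c(10, 30),
                                              large = c(50, Inf)),
                               seed = 1L) {
  stopifnot(is.list(grids), length(grids) == length(gsw))
  if (length(grids) < 3L) stop("fewer than 3 paired observations")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  rows <- lapply(seq_along(regimes), function(r) {
    rng <- regimes[[r]]
    set.seed(derive_seed(seed, r))
    sampled <- vapply(seq_along(grids), function(i) {
      v <- valid_sd(grids[[i]])
      lo <- max(1L, as.integer(rng[1]))
      hi <- as.integer(min(rng[2], length(v)))
      if (hi < lo) hi <- lo <- min(lo, length(v))
      n <- if (hi > lo) sample(lo:hi, 1L) else lo
      mean(v[sample.int(length(v), n)])
    }, numeric(1))
    fit <- stats::lm(gsw ~ sampled)
    sm <- summary(fit)
    data.frame(regime = names(regimes)[r],
               n_pairs = length(gsw),
               slope = unname(coef(fit)[2L]),
               intercept = unname(coef(fit)[1L]),
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2L, 4L])
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
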