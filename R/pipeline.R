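#' Pipeline configuration
#'
#' All tunable parameters of the imaging pipeline in one flat, validated
#' list.  Defaults are the standard operating point of the workflow:
#' CLAHE block 127 with 256 bins and slope limits 8--14, median radius 8,
#' Moments/Li particles of 800--4000 um^2 and Minimum particles of
#' 800--3000 um^2 with circularity 0.5--0.9, Percentile exclusion masking
#' above 400 000 um^2, 1 mm^2 grid cells, k = 4 spatial weights, and a
#' 1000-iteration sampling simulation with the 10% error / 95% coverage
#' criteria.
#'
#' @param pixel_size_um image calibration (um per pixel).
#' @param clahe a [clahe_params()].
#' @param median_size median filter radius in pixels.
#' @param rules list of [threshold_rule()] objects.
#' @param exclusion_min_area_um2 minimum excluded-component area.
#' @param merge_radius_um detection de-duplication radius.
#' @param cell_size_mm grid cell edge.
#' @param k spatial-weights neighbour count.
#' @param iterations sampling-simulation iterations.
#' @param max_rel_err,min_coverage minimum-sampling criteria.
#' @param seed integer seed for stochastic stages.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size_um = 1.11,
                            clahe = clahe_params(),
                            median_size = 8L,
                            rules = threshold_rules(),
                            exclusion_min_area_um2 = 400000,
                            merge_radius_um = 25,
                            cell_size_mm = 1,
                            k = 4L,
                            iterations = 1000L,
                            max_rel_err = 0.10,
                            min_coverage = 0.95,
                            seed = 1L) {
  stopifnot(pixel_size_um > 0, inherits(clahe, "clahe_params"),
            median_size >= 0, length(rules) >= 1L,
            all(vapply(rules, inherits, logical(1), "threshold_rule")),
            exclusion_min_area_um2 > 0, merge_radius_um >= 0,
            cell_size_mm > 0, k >= 1L, iterations >= 1L,
            max_rel_err > 0, 0 < min_coverage, min_coverage <= 1)
  structure(list(pixel_size_um = pixel_size_um, clahe = clahe,
                 median_size = as.integer(median_size), rules = rules,
                 exclusion_min_area_um2 = exclusion_min_area_um2,
                 merge_radius_um = merge_radius_um,
                 cell_size_mm = cell_size_mm, k = as.integer(k),
                 iterations = as.integer(iterations),
                 max_rel_err = max_rel_err, min_coverage = min_coverage,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly; the reader returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- list(
    pixel_size_um = config$pixel_size_um,
    clahe = unclass(config$clahe),
    median_size = config$median_size,
    rules = lapply(config$rules, unclass),
    exclusion_min_area_um2 = config$exclusion_min_area_um2,
    merge_radius_um = config$merge_radius_um,
    cell_size_mm = config$cell_size_mm,
    k = config$k,
    iterations = config$iterations,
    max_rel_err = config$max_rel_err,
    min_coverage = config$min_coverage,
    seed = config$seed)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    pixel_size_um = y$pixel_size_um,
    clahe = do.call(clahe_params, y$clahe),
    median_size = y$median_size,
    rules = lapply(y$rules, function(r) do.call(threshold_rule, r)),
    exclusion_min_area_um2 = y$exclusion_min_area_um2,
    merge_radius_um = y$merge_radius_um,
    cell_size_mm = y$cell_size_mm,
    k = y$k,
    iterations = y$iterations,
    max_rel_err = y$max_rel_err,
    min_coverage = y$min_coverage,
    seed = y$seed)
}

#' Run the full image-to-statistics pipeline
#'
#' Chains preprocessing, exclusion masking, stomata detection, 1 mm^2
#' density gridding and spatial statistics for each input image, writing
#' per-stage artifacts and a machine-readable manifest to `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param images named list of inputs: file paths, [leaf_image] objects,
#'   or lists of planes (max-projected first).
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param verbose log per-stage counts.
#' @return list of per-image result bundles (preprocessed image omitted),
#'   each with `detections`, `mask_area_mm2`, `density_mm2`, `grid`,
#'   `stats`, `timings`; plus `manifest`.
#' @export
run_pipeline <- function(config, images, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"), length(images) >= 1L)
  if (is.null(names(images)))
    names(images) <- sprintf("image%02d", seq_along(images))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  results <- list()
  manifest <- list(package = "stomamap",
                   version = as.character(utils::packageVersion("stomamap")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   images = list())
  if (!is.null(out_dir)) {
    cfg_path <- file.path(out_dir, "config.yaml")
    write_pipeline_config(config, cfg_path)
    manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  }
  for (nm in names(images)) {
    stage <- "load"
    bundle <- tryCatch({
      timings <- c()
      tic <- function() proc.time()[["elapsed"]]
      t0 <- tic()
      x <- images[[nm]]
      img <- if (is.character(x))
        read_leaf_image(x, pixel_size_um = config$pixel_size_um)
      else if (is.list(x) && !is_leaf_image(x)) max_project(x)
      else x
      stopifnot(is_leaf_image(img))
      timings["load"] <- tic() - t0

      stage <- "preprocess"; t0 <- tic()
      pre <- preprocess_image(img, config$clahe, config$median_size)
      timings["preprocess"] <- tic() - t0

      stage <- "exclusion"; t0 <- tic()
      mask <- exclusion_mask(pre, config$exclusion_min_area_um2)
      timings["exclusion"] <- tic() - t0

      stage <- "detect"; t0 <- tic()
      det <- detect_stomata(pre, config$rules, mask, config$merge_radius_um)
      timings["detect"] <- tic() - t0
      say("[%s] detected %d stomata (per rule: %s); %.2f mm^2 excluded",
          nm, nrow(det),
          paste(names(attr(det, "n_per_rule")), attr(det, "n_per_rule"),
                sep = "=", collapse = ", "),
          mask$excluded_area_um2 / 1e6)

      stage <- "grid"; t0 <- tic()
      grid <- grid_density(det, mask, cell_size_mm = config$cell_size_mm,
                           meta = list(image = nm))
      timings["grid"] <- tic() - t0

      stage <- "stats"; t0 <- tic()
      total_um2 <- prod(dim(pre)) * pixel_size(pre)^2
      dens <- stomatal_density(nrow(det), total_um2, mask$excluded_area_um2)
      w <- knn_weights(grid, config$k)
      li <- local_morans_i(grid, w)
      dev <- relative_global_deviation(grid)
      stats <- list(n_stomata = nrow(det),
                    total_area_um2 = total_um2,
                    excluded_area_um2 = mask$excluded_area_um2,
                    density_mm2 = dens,
                    n_valid_cells = sum(grid$valid),
                    global_i = global_morans_i(grid, w),
                    mean_local_i = attr(li, "mean_local_i"),
                    mean_d_rel = dev$mean_d_rel,
                    cv_percent = dev$cv_percent)
      timings["stats"] <- tic() - t0
      say("[%s] density %.1f mm^-2 over %d valid cells; global I = %.3f",
          nm, dens, stats$n_valid_cells, stats$global_i)

      outputs <- character(0)
      if (!is.null(out_dir)) {
        stub <- file.path(out_dir, nm)
        write_detections_csv(det, paste0(stub, "_detections.csv"))
        write_mask_png(mask, paste0(stub, "_mask.png"))
        write_grid_csv(grid, paste0(stub, "_grid.csv"))
        render_heatmap(grid, paste0(stub, "_heatmap.png"))
        jsonlite::write_json(stats, paste0(stub, "_summary.json"),
                             auto_unbox = TRUE, digits = NA)
        outputs <- paste0(basename(stub),
                          c("_detections.csv", "_mask.png", "_grid.csv",
                            "_heatmap.png", "_summary.json"))
      }
      list(detections = det, mask_area_mm2 = mask$excluded_area_um2 / 1e6,
           density_mm2 = dens, grid = grid, stats = stats,
           timings = timings, outputs = outputs)
    }, error = function(e) {
      stop(sprintf("pipeline failed at stage '%s' for input '%s': %s",
                   stage, nm, conditionMessage(e)), call. = FALSE)
    })
    results[[nm]] <- bundle
    manifest$images[[nm]] <- list(outputs = bundle$outputs,
                                  timings = as.list(bundle$timings),
                                  n_stomata = bundle$stats$n_stomata)
  }
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

#' Validate detections against ground truth
#'
#' Greedy nearest-neighbour matching: ground-truth points are visited in
#' row-major order (top-to-bottom, then left-to-right) and each is paired
#' with the nearest not-yet-matched detection within `match_radius_um`.
#' Recall is the matched fraction of truth, precision the matched
#' fraction of detections.
#'
#' @param detections data frame with `centroid_x_um` / `centroid_y_um`.
#' @param truth data frame with `centroid_x_um` / `centroid_y_um`.
#' @param match_radius_um maximum matching distance (default 25 um).
#' @return list with `recall`, `precision`, `n_matched`, `n_truth`,
#'   `n_detected`, and a `matches` data frame (truth row, detection row,
#'   distance).
#' @export
validate_against_truth <- function(detections, truth, match_radius_um = 25) {
  n_truth <- nrow(truth)
  n_det <- nrow(detections)
  if (n_truth == 0L) stop("empty ground truth")
  if (n_det == 0L) {
    warning("no detections; precision undefined, reported as 0")
    return(list(recall = 0, precision = 0, n_matched = 0L,
                n_truth = n_truth, n_detected = 0L,
                matches = data.frame(truth = integer(0),
                                     detection = integer(0),
                                     distance_um = numeric(0))))
  }
  ord <- order(truth$centroid_y_um, truth$centroid_x_um)
  free <- rep(TRUE, n_det)
  dx <- detections$centroid_x_um
  dy <- detections$centroid_y_um
  m_truth <- integer(0); m_det <- integer(0); m_dist <- numeric(0)
  for (i in ord) {
    d2 <- (dx - truth$centroid_x_um[i])^2 + (dy - truth$centroid_y_um[i])^2
    d2[!free] <- Inf
    j <- which.min(d2)
    if (d2[j] <= match_radius_um^2) {
      free[j] <- FALSE
      m_truth <- c(m_truth, i); m_det <- c(m_det, j)
      m_dist <- c(m_dist, sqrt(d2[j]))
    }
  }
  list(recall = length(m_truth) / n_truth,
       precision = length(m_truth) / n_det,
       n_matched = length(m_truth),
       n_truth = n_truth, n_detected = n_det,
       matches = data.frame(truth = m_truth, detection = m_det,
                            distance_um = m_dist))
}
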