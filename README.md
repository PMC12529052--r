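# stomamap

Large-area stomatal density mapping from chlorophyll autofluorescence
images.

Stomata regulate the trade-off between CO₂ uptake and water loss, and
their density (SD, stomata mm⁻²) varies across a leaf — between the
adaxial and abaxial surfaces, from base to tip, and patchily within a
surface. Quantifying that heterogeneity requires counting stomata over
square centimetres, far beyond what peels or impressions sample.
`stomamap` is an R package for researchers doing exactly that with
fluorescence microscopy: in chlorophyll autofluorescence images the
mesophyll glows and stomata appear as dark ellipses, so they can be
detected without staining or peeling.

The package implements the full quantification chain:

* **Preprocessing** — maximum-intensity projection, contrast-limited
  adaptive histogram equalization (CLAHE; block 127 px, 256 bins, slope
  8–14) and a radius-8 median filter.
* **Detection** — automatic thresholding by three classical algorithms
  (Tsai's Moments, Li's minimum cross-entropy, the Prewitt–Mendelsohn
  Minimum), each followed by particle filtering on area (800–4000 µm²;
  800–3000 µm² for Minimum) and circularity 4πA/P² ∈ [0.5, 0.9], with
  the per-rule detections merged within 25 µm. Veins, borders and
  degraded regions are removed by Percentile-threshold exclusion masking
  (dark components above 400 000 µm²), and
  SD = n / (total − excluded area).
* **Gridding** — SD per 1 mm² cell against per-cell available area, with
  fixed-scale (0–150 mm⁻², blue→red) annotated heatmaps.
* **Spatial statistics** — per-cell relative global deviation
  |SD<sub>i</sub> − S̄D| / S̄D, coefficient of variation, and global and
  local Moran's *I*:

  I = (n/W) · Σᵢ Σⱼ wᵢⱼ zᵢ zⱼ / Σᵢ zᵢ², Iᵢ = zᵢ · Σⱼ wᵢⱼ zⱼ,  zᵢ = SDᵢ − S̄D,

  over binary k-nearest-neighbour weights (k = 4), with replicate maps
  aggregated by cellwise medians.
* **Sampling simulation** — 1000-iteration Monte Carlo subsampling
  without replacement at every sample size, reporting relative error and
  95% t-interval coverage, the minimum sampling requirement (≤ 10% mean
  relative error *and* ≥ 95% coverage), and structure–function
  regressions under small / medium / large sampling regimes with
  Benjamini–Hochberg-adjusted p-values.
* **Synthetic leaves** — a seeded generator of autofluorescence-style
  images (dark elliptical stomata in parallel files with a base→tip
  density gradient, vein stripes, border frame, speckle) with exact
  ground-truth centroids, so every stage is testable end to end.

## Worked example

```r
library(stomamap)

spec <- synthetic_leaf_spec(width_mm = 3, height_mm = 3,
                            base_density_mm2 = 60, tip_density_mm2 = 90,
                            seed = 7)
leaf <- generate_leaf_image(spec)
leaf
#> <synthetic_leaf> 2703 x 2703 px, 468 stomata, 6.31 mm^2 available

pre  <- preprocess_image(leaf$image)      # CLAHE + median filter
mask <- exclusion_mask(pre)               # veins + border, > 400000 um^2
det  <- detect_stomata(pre, mask = mask)  # Moments / Li / Minimum union

v <- validate_against_truth(det, leaf$truth)
sprintf("detected %d of %d stomata (recall %.3f, precision %.3f)",
        v$n_matched, v$n_truth, v$recall, v$precision)
#> "detected 467 of 468 stomata (recall 0.998, precision 0.994)"

stomatal_density(nrow(det), prod(dim(pre)) * pixel_size(pre)^2,
                 mask$excluded_area_um2)
#> 75.4  # stomata per mm^2 of available leaf area

grid <- grid_density(det, mask)           # 1 mm^2 cells
grid
#> <density_grid> 4 x 4 cells of 1 mm, 9 valid; mean SD 75.7

w   <- knn_weights(grid, k = 4)
dev <- relative_global_deviation(grid)
c(global_i = global_morans_i(grid, w),
  mean_d_rel = dev$mean_d_rel, cv_percent = dev$cv_percent)
#> global_i = 0.228   mean_d_rel = 0.095   cv_percent = 11.7

sim <- subsample_population(grid$sd[grid$valid], iterations = 1000,
                            seed = 42)
min_sampling_requirement(sim)$n_min
#> 2  # cells needed for <=10% error and >=95% CI coverage
```

Reading the numbers: the detector recovered 467 of the 468 rendered
stomata and reported a density of 75.4 mm⁻² (the generator's gradient
averages 75 mm⁻² over this segment). The mildly positive global Moran's
*I* (0.228) reflects the base→tip gradient — neighbouring cells have
similar densities; a value near zero would mean spatial randomness,
negative values local outliers. The mean relative global deviation
(0.095) and CV (11.7%) summarise how heterogeneous the cells are, and
for this nearly uniform little segment two 1 mm² cells already estimate
the mean density to within 10% with nominal coverage.

A command-line interface wrapping the same functions ships in
`inst/cli/stomamap` (verbs: `simulate`, `preprocess`, `detect`, `grid`,
`stats`, `sample-sim`, `validate`, `run`).

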