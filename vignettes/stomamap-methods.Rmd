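---
title: "Mapping stomatal density and its spatial structure from chlorophyll autofluorescence images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping stomatal density and its spatial structure from chlorophyll autofluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stomamap)
```

## The measurement problem

Stomata — the pores through which a leaf exchanges CO~2~ and water vapour —
are distributed non-uniformly over a leaf surface, and in grasses such as
barley they differ between the upper (adaxial) and lower (abaxial)
epidermis and along the base-to-tip axis. Classical counting methods
(epidermal peels, impressions) sample a millimetre-scale field of view, so
they cannot resolve this heterogeneity, and they cannot say how much leaf
area one must sample before a density estimate is trustworthy.

Chlorophyll autofluorescence offers a label-free contrast mechanism:
mesophyll fluoresces brightly under blue excitation, whereas stomatal guard
cells, with few chloroplasts and thick walls, appear as dark ellipses.
`stomamap` implements a complete quantification chain for such images:

1. **preprocess** — maximum-intensity projection of a focal stack, local
   contrast enhancement (CLAHE), median filtering;
2. **detect** — multi-method automatic thresholding with particle-level
   area and circularity gates, plus percentile-threshold masking of
   regions that cannot bear stomata (veins, leaf borders, degraded
   tissue);
3. **grid** — stomatal density per 1 mm² cell, each cell normalised by
   its own available (non-excluded) area;
4. **spatial statistics** — relative global deviation, coefficient of
   variation, global and local Moran's *I* over k-nearest-neighbour
   weights;
5. **sampling simulation** — Monte Carlo subsampling of the gridded
   densities to find the minimum leaf area for a reliable estimate.

A seeded synthetic-leaf generator with exact ground truth makes the whole
chain testable without microscope data.

## Preprocessing

CLAHE equalizes the histogram within square blocks (default edge
127 px ≈ 141 µm at the default calibration of 1.11 µm per pixel) using
256 bins, and interpolates the per-block transfer functions bilinearly
between block centres (the "fast" variant). The contrast-limit slope is
constrained to the working range [8, 14]; the default working slope is
the midpoint, 11. The slope bounds the steepness of the local intensity
transfer: mass above the corresponding histogram clip is redistributed
uniformly, which deliberately *limits* how far a near-uniform region can
be stretched. A consequence worth knowing: a two-tone image is not
stretched to the full bit depth — local contrast is amplified severalfold
while the global range stays close to the input range. All three CLAHE
values are exposed because image quality (leaf flatness, bleaching)
varies between acquisitions.

The median filter uses a square window of radius 8 px with edge
replication, computed with a constant-time sliding-window algorithm. At
this radius the difference between a square and a circular window is
immaterial for objects the size of a stoma (roughly 54 × 22 px); the
square window was chosen because it has an exact O(1)-per-pixel
implementation. Internally both steps work in normalized float and
re-quantize to the native bit depth, so the downstream histogram
thresholds always see the full 8- or 16-bit range.

## Detection

Stomata do not fluoresce, so every threshold keeps the *dark* side of its
cut. Three classical auto-threshold algorithms are applied independently
to the same preprocessed image: Tsai's moment-preserving threshold, Li &
Tam's minimum-cross-entropy fixed point, and the Prewitt–Mendelsohn
"minimum" mode method (smooth the 256-bin histogram with a running mean
of three until exactly two strict local maxima remain, cut at the valley).
Each binary is labelled with 8-connected components and filtered by:

* **area** — 800–4000 µm² for Moments and Li, 800–3000 µm² for Minimum;
* **circularity** — 4π·area/perimeter² in [0.5, 0.9] for all rules.

The perimeter uses a two-direction Crofton estimator,
π/4 × (horizontal + vertical boundary transitions), which is unbiased
for smooth convex shapes. Under this estimator a rasterised disk has
circularity ≈ 1.0 and is *rejected* by the 0.9 ceiling — the gate
anticipates the elongated outline of a grass stomatal complex, and the
estimator is central enough to the gate that it is documented here:
substituting a boundary-pixel-count perimeter would shift circularities
down by tens of percent and invalidate the printed gate.

The per-rule detections are pooled in the order Moments, Li, Minimum and
merged: a detection within 25 µm (about half a stoma length) of an
already accepted one is dropped, the earliest rule winning. Finally any
detection whose centroid pixel lies inside the exclusion mask is removed.
A rule whose threshold fails (e.g. Minimum on a histogram that never
becomes bimodal) is skipped with a warning; detection fails only when
every rule fails.

**Exclusion masking.** Regions that cannot bear stomata are found by
percentile thresholding (dark side, target fraction 0.5) followed by a
morphological opening (disc of radius 5 px) and a component-area gate:
8-connected dark components larger than 400 000 µm² become the mask. The
opening is a robustness device with a geometric rationale: veins and
borders are *solid* dark structures, whereas the percentile cut — which
by construction marks about half of all pixels on a structure-free image
— links background pixels into sprawling filamentous clusters. Opening
shatters those filaments (their necks are a few pixels wide) while
leaving 100-µm-scale veins untouched; on synthetic leaves it also trims
the fringe of dark speckle that otherwise accretes onto vein components.

**Density.** Stomatal density is the stoma count divided by the
*available* area — total imaged area minus the excluded area — in
stomata mm⁻².

## Gridding

Cells are half-open 1 mm² squares anchored at the image origin (the
anchoring is a convention; the underlying data do not fix it). Counting
is centroid-in-cell, which cannot double-count. Each cell's available
area is its geometric area minus excluded and out-of-extent pixels; a
cell below 50% available area is flagged *invalid* and its density is
undefined (`NA`), never zero — partial border slivers would otherwise
report inflated or deflated densities. Heatmaps use a fixed spectral
scale, blue = 0 to red = 150 stomata mm⁻² by default, so that maps of
different leaves are directly comparable; autoscaling is available for
other species.

## Spatial statistics

Let SD~i~ be the density of valid cell *i*, and
$\bar{SD}$ the mean over the valid cells of the group (genotype ×
surface × position × replicate — the grid carries these labels).

* **Relative global deviation**: per cell
  $D^{rel}_i = |SD_i - \bar{SD}| / \bar{SD}$, a unitless heterogeneity
  map; its mean is the group summary. The absolute value follows the
  metric's definition as an *absolute* deviation; the signed map is kept
  for diagnostics.
* **Coefficient of variation**: 100 × sample SD / mean over valid cells.
* **Global Moran's I** over binary, directed k-nearest-neighbour weights
  (k = 4, Euclidean distances between valid cell centres, ties broken by
  row-major cell index):
  $I = \frac{n}{W}\,\frac{\sum_i \sum_j w_{ij} z_i z_j}{\sum_i z_i^2}$,
  with $z_i = SD_i - \bar{SD}$ and $W = \sum_{ij} w_{ij} = nk$. The
  weights are deliberately *not* row-standardized: the explicit $n/W$
  prefactor in the formula is redundant under row-standardization, and
  with equal row sums (every cell has exactly k neighbours) the two
  parameterisations coincide anyway — a property the test suite uses to
  cross-check against an independent library implementation.
* **Local Moran's I**: the raw product form
  $I_i = z_i \sum_j w_{ij} z_j$, which satisfies
  $I = (n/W) \sum_i I_i / \sum_i z_i^2$ exactly. The conventional LISA
  variant (division by $m_2 = \sum z^2 / n$) is available behind an
  off-by-default flag; the raw form is the default because it is the
  form the summary statistics are defined on.
* **Replicate aggregation**: maps are aligned at their top-left valid
  anchor, cropped to the common intersection, and combined by cellwise
  medians; a cell is valid in the output when valid in at least half the
  replicates.

Invalid cells are removed from *n*, *W*, $\bar{SD}$ and every sum — they
are never zero-filled. A constant grid raises an explicit
zero-variance error rather than returning 0 or NaN.

## Sampling simulation

For every sample size n from 1 to the number of valid cells N, the
simulator draws 1000 random subsets without replacement and records the
sample mean, its dispersion, the mean absolute and relative error
against the population mean, the mean standard error, and the fraction
of iterations whose 95% t-interval covers the population mean. The
*minimum sampling requirement* is the smallest n that simultaneously
achieves ≤ 10% mean relative error and ≥ 95% coverage. Since a
t-interval needs two observations, n = 1 is defined to fail the coverage
criterion; a perfectly uniform leaf therefore floors at **two** 1 mm²
cells without special-casing.

Two calibration facts shape the interpretation:

* On an effectively infinite Gaussian population the t-interval is
  nominal, and the mean relative error follows c/√n closely (the test
  suite fits R² > 0.95 over n ∈ [2, N/2]).
* Because draws are *without replacement*, the uncorrected t-interval
  becomes conservative as the sampling fraction grows: coverage drifts
  above 97% beyond roughly a tenth of the population and reaches 100% at
  the census size, where every sample reproduces the population mean
  exactly. Nominal-coverage checks are therefore meaningful only at
  small sampling fractions; the package intentionally does not apply a
  finite-population correction, matching how such intervals are used in
  practice.

Determinism: each sample size draws from its own seed sub-stream
(derived as `(seed*48271 + 7919*n) mod 2147483629`), so results are
identical whether sizes are simulated serially, in parallel, or in
subsets.

**Sampling regimes.** To show how sampling intensity distorts
structure–function relationships, `regime_correlation()` pairs each
density grid with a gas-exchange observation (e.g. stomatal conductance
g~sw~), estimates each leaf's density from a seeded random draw of cells
— 1–3 cells for the "small" regime, 10–30 for "medium", 50+ for "large"
— and regresses g~sw~ on the sampled densities. Slope p-values are
Benjamini–Hochberg adjusted across the regressions of the call. With a
noiseless linear link, the census regime recovers the slope exactly
while the small regime attenuates R² — the mechanism behind the
observation that small sampling areas produce weak, unstable
correlations. Half-cell areas are not representable in gridded
matrices, so the small regime maps to 1–3 whole cells.

## The synthetic leaf generator

`synthetic_leaf_spec()` describes a rectangular leaf segment: bright
mesophyll background (45% of the bit-depth range) with multiplicative
Gaussian speckle (sd 15%) smoothed by a σ = 1.5 px Gaussian to mimic
correlated texture; dark longitudinal vein stripes (3 veins of 120 µm by
default) and a 150 µm dark border frame, rendered at the same intensity
as stomata (25% of background) so that exclusion masking is genuinely
exercised; and dark elliptical stomata of 60 × 24 µm (area ≈ 1131 µm²,
aspect 2.5 — the elongated outline of a grass guard-cell complex, which
also places detected circularities comfortably inside the [0.5, 0.9]
gate after threshold halo growth).

Stomata are arranged in parallel files 64 µm apart with a random phase
per seed. Along a file they form a hard-core renewal process: successive
centres are separated by one stoma length plus a guaranteed edge-to-edge
clearance of another stoma length, plus an exponential gap whose rate is
chosen so the local mean spacing matches the requested density — a
linear base-to-tip gradient evaluated at the current position. Files
keep a 25 µm clear zone from veins and borders, emulating the
stomata-free costal zones of grass leaves; without it, threshold halos
merge vein-adjacent stomata into the vein component and no contrast
setting reaches realistic detection rates. The default contrast
(stoma intensity 25% of background, speckle 15%) was chosen once, during
generator calibration, so that the printed auto-thresholds separate the
dark and bright modes of the preprocessed histogram.

Because density is defined per *available* area while centres are
confined to the admissible (clear-zone) region, each file's intensity is
scaled by the local available/admissible length ratio on the canonical
1 mm cell grid, and gaps are drawn with a half-gap lookahead. This makes
the expected stoma count of every cell equal
`expected_density_field(spec) × cell available area` — the analytic
oracle the test suite checks cell-by-cell (within three standard errors
over 30 seeds). The corrections are capped at the hard-core packing
limit, so extremely narrow sliver cells can come out slightly
under-dense; the cap also defines the generator's feasibility bound
(with the default geometry, uniform densities up to ≈ 105 mm⁻² are
representable).

What the generator does **not** emulate: optical point-spread blur
beyond the small Gaussian, tile stitching seams, dumbbell guard-cell
morphology (ellipses satisfy the detector's contract), curvature-induced
defocus, and real biological clustering beyond the hard-core file
structure. Passing detection tests on these images therefore validates
the *pipeline logic* — thresholds, gates, masking, bookkeeping — not the
detector's robustness to every real-world artefact.

## Numerical and interface conventions

* Pixel indices are 0-based with origin top-left and x = column;
  physical coordinates are pixel centre × pixel size, in µm.
* `auto_threshold()` returns a 1-based bin index b; the dark side is
  bins 1..b. Percentile tie rule: the smallest bin whose cumulative
  fraction reaches the target. Moments tie rule: the smallest bin whose
  cumulative fraction reaches the moment-preserving dark fraction p0.
* Grid CSVs are plain rectangular numeric matrices with empty fields
  marking invalid cells; metadata travels in a sidecar JSON. Ragged or
  non-numeric files raise errors naming the offending row.
* All randomness flows from integer seeds through fixed sub-stream
  derivations; identical seeds give bit-identical images, detections and
  simulation tables.

## Problem sizes

The bundled tests and the acceptance script run entirely on synthetic
data at desk scale: ten 4 × 4 mm leaves (3604² pixels at 1.11 µm/px)
for detector validation, 2–2.5 mm leaves for module tests, grids up to
8 × 8 cells for exact spatial-statistics oracles, and N = 400 cell
populations with 1000 Monte Carlo iterations for the sampling
calibration. These sizes were chosen so the whole suite completes in a
few minutes while every statistical check retains adequate power; all
of them scale linearly in pixels or cells if larger runs are wanted.

## Known limitations

* Only stomata are quantified — no apertures, guard-cell or pavement-cell
  measurements.
* The exclusion percentile fraction (0.5) and the merge radius (25 µm)
  are conventions, exposed as parameters.
* Whether the original iterative-thresholding workflow removed detected
  particles between passes is unknowable from the description; this
  implementation applies the rules independently and unions the results.
* The local Moran's I default omits the m₂ normalisation of the
  conventional LISA (the printed summary form); enable `standardized =
  TRUE` for comparisons with standard LISA software.
* Replicate-level error estimates printed beside aggregated local
  Moran's I values in source material are of ambiguous type (SD vs SE);
  this package reports plain means and leaves dispersion to the caller.
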