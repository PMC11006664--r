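---
title: "Mapping Posidonia oceanica meadows from multispectral imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping Posidonia oceanica meadows from multispectral imagery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

posimap maps the Mediterranean seagrass *Posidonia oceanica* (PO) from
multi-date shallow-water surface-reflectance imagery (in practice,
atmospherically corrected Sentinel-2 RGB bands at 10 m) together with a
bathymetry grid, and monitors the mapped meadows across years. This vignette
is the package's own account of the method: the model at each stage, the
tunable parameters and why their defaults are what they are, what the
synthetic-scene simulator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The mapping problem

PO forms dense meadows on sandy and rocky bottoms at 0–40 m depth. In
clear oligotrophic water the bottom is visible to a satellite in the blue
and green bands down to roughly 25 m, beyond which attenuation makes PO and
bare bottom progressively harder to distinguish. The classification is
therefore depth-confounded by construction: the same bottom looks different
at different depths, and different bottoms can look alike at depth. Rather
than inverting the water column explicitly (an approach that becomes
unstable in deep water), the classifier receives depth as a feature and
learns the joint colour–depth relation of vegetated and unvegetated
bottoms implicitly.

## Pipeline stages

### Screening and median compositing

A year's archive (typically 3–9 usable acquisitions) is screened
automatically: a date is dropped when its no-data fraction exceeds
`max_masked_fraction` (default 0.3) or when any per-band spatial mean lies
more than `band_anomaly_z` (default 3) robust z-scores — median and
1.4826·MAD across dates — from the archive median. This is a quantitative
stand-in for the visual quality control a human operator would apply; its
thresholds are engineering defaults, not calibrated constants, and every
rejection is logged with its reason.

The retained dates are reduced to one composite by a per-pixel, per-band
**median** over the dates where the pixel is valid. The median is the
load-bearing robustness device: any transient that strikes a strict
minority of dates at a pixel — a boat, a swell crest, residual glint —
leaves the odd-count composite bit-identical to the artifact-free one.
Pixels observed fewer than `min_valid` times (default 3, mirroring the
usual minimum archive depth per year) become invalid. An even observation
count takes the midpoint of the two central values, the standard median
definition.

### Bathymetry and the 40 m crop

Bathymetry usually arrives coarser than the imagery (e.g. 100 m) and is
resampled to the analysis grid by bilinear interpolation of the four
nearest coarse-cell centres; fine pixels outside the coarse centre extent
are invalid. Depth is positive-down metres everywhere in the package.
Pixels deeper than `crop_depth` (default 40 m, the depth limit of the
species) are removed before classification, because optically deep water
and dense meadow have confusably similar spectra. The boundary is
**inclusive**: a pixel at exactly 40 m is retained, since the species
limit is "down to 40 m". The crop is idempotent and configurable.

### Ground truth rasterization

Habitat cartography arrives as labelled polygons (GeoJSON). A pixel takes
the class of the polygon containing its **centre** — the cheapest rule
with an exact brute-force oracle, which the tests exercise on circles and
squares. Habitat classes map to PO = 1 / Non-PO = 0 through a user-supplied
class map; an unmapped class is a loud error rather than a silent Non-PO.
Where overlapping polygons claim one centre the last-listed wins, with a
warning counting the conflicts. Pixel centres covered by no polygon are
*unknown*: excluded from training and from accuracy assessment (real
cartographies are incomplete), but still predicted.

### The pixel-wise neural network

Each valid pixel contributes a feature vector (blue, green, red, depth).
Features are z-score standardized with statistics computed over the
training table — required for stable gradient descent when reflectance
(~0.01–0.3) and depth (0–40 m) share a network. The classifier is a
feed-forward network: affine map then rectified linear unit (ReLU) through
the hidden layers, a single sigmoid output giving the probability of PO,
thresholded at 0.5. A probability of exactly 0.5 maps to PO; the tie rule
is documented because either reading of "threshold 0.5" is defensible.

Training minimizes binary cross-entropy — the canonical loss for a sigmoid
output — by plain mini-batch gradient descent: the labelled table is split
80/20 into training and validation, batches are drawn in a seeded shuffled
order each epoch, and the gradient of each batch updates all layers by
backpropagation. The returned model is the per-epoch snapshot with minimum
validation loss. Rows are canonicalized by pixel index before the seeded
shuffle, so results do not depend on the caller's row order; changing the
seed changes the initialization and hence the fit.

Defaults — two hidden layers of 32 and 16 units, batch 256, learning rate
0.05, 300 epochs — are engineering choices: the smallest shape that
reliably learns the nonlinear colour–depth interaction on the synthetic
scenes, logged in the model file so any map can be traced to its
hyperparameters. Depth enters raw (standardized), untransformed. Trained
models persist as versioned JSON carrying layer sizes, weights, biases,
scaling, threshold and seed at full floating-point precision, so a
reloaded model reproduces its forward outputs bit-identically.

### Post-filtering

Four candidate filters clean the binary map:

* **median** (default, 3×3): majority class in the truncated window over
  valid pixels; an exact tie keeps the centre's class (stability bias).
  This is the filter that best removes isolated misclassified pixels while
  preserving patch shape.
* **sieve**: 4-connected components smaller than `min_size` are relabelled
  to their largest adjacent component's class, ties broken toward Non-PO
  (the conservative mapping).
* **bilateral**: Gaussian-spatial × Gaussian-range weighted mean,
  re-thresholded at 0.5 to stay binary. Note that with a tight range sigma
  (default 0.2) the range kernel suppresses cross-class weights almost
  entirely — the filter is edge-preserving by design and therefore keeps
  isolated single pixels; only with a large range sigma does it degenerate
  to a Gaussian mean and remove them. The tests pin both regimes.
* **PCA**: the multi-band composite (not the binary map) is projected onto
  its top principal components and reconstructed, discarding low-variance
  noise before classification.

Sieve size, bilateral sigmas and component count have no calibrated
values; they are exposed for experimentation. Per-tile maps are filtered
first and then mosaicked; where overlapping tiles disagree, PO wins — the
mosaic never erases detected meadow — and disagreements are counted in a
warning so users can audit the rule.

### Accuracy assessment

Three statistics, computed from the per-pixel confusion counts over pixels
valid in both map and truth:

* overall accuracy (TP + TN)/n,
* producer's accuracy TP/(TP + FN) — how often true PO is detected,
* user's accuracy TP/(TP + FP) — how often mapped PO is truly PO.

A statistic with an empty denominator is reported as not applicable, never
as zero. Reports are stratified by depth, by default 0–25 m and 25–40 m;
bins are (low, high] with the 0 m bin closed at 0, so the 25 m boundary
belongs to the shallow bin. Unknown-truth pixels are excluded from all
statistics rather than treated as Non-PO. The per-pixel performance map
(TP/TN/FP/FN/unknown) uses documented integer codes and is always
consistent with the counts. Assessment can run on the 20 % validation
split (the default, reported as such) or on all labelled pixels.

### Change assessment

Two yearly maps compare pixel-wise to gain (0→1), loss (1→0), no-change,
or unknown (either year invalid); areas are pixel counts ×
pixel_size²/10⁶ km², computed in that operation order so integer-valued
counts convert exactly. Over a series, the per-pixel transition count is
the number of consecutive-year pairs that change class; pairs with an
invalid year are skipped and flagged in a quality raster rather than
interpolated. A transition count of 0 logically covers both always-PO and
always-bare pixels, so the always-PO subset is additionally flagged —
stable meadow is the quantity of conservation interest. The display
binning is 0 / 1 / 2 / ≥3.

## The synthetic scene

The simulator generates the inputs the pipeline would otherwise download:

* **bathymetry**: a smooth west-shore-to-east-deep ramp plus a
  low-frequency random field, positive-down, in (0, max_depth];
* **habitat truth**: a smooth random field thresholded at the
  cover-fraction quantile inside the ≤ depth-limit zone, giving contiguous
  blob patches, never deeper than the species limit;
* **reflectance**: the two-flow exponential shallow-water model
  R(λ) = R∞(λ) + (A(λ) − R∞(λ))·exp(−2K(λ)z) + ε with per-band Gaussian
  noise, clipped to [0, 1];
* **artifacts**, per date: single-pixel bright outliers (boats), additive
  sinusoidal stripes at a random angle on a random subset of dates
  (swell), one rectangular no-data patch of approximately the requested
  area (cloud), and a per-band additive offset drawn uniformly within the
  seasonal amplitude.

The default optical constants — PO canopy (0.030, 0.060, 0.030), sand
(0.200, 0.250, 0.220), deep-water reflectance (0.020, 0.010, 0.005),
attenuation (0.040, 0.060, 0.300) m⁻¹ for blue/green/red — are synthetic
choices shaped to clear Mediterranean-like water: dark canopy under bright
sand, red extinguished within metres, blue carrying signal deepest. They
are not calibrated to any instrument. Noise defaults to 0.005 per band.
The default scene is 256×256 pixels at 10 m with 6 dates, 35 % cover and
a 40 m species limit; every generator is bit-reproducible from its seed.

What the simulator does **not** emulate: radiative-transfer realism (no
BRDF, no sun geometry, no inelastic scattering), atmospheric residuals,
spatial autocorrelation of sensor noise, mixed pixels at meadow edges,
within-class albedo variability, or seasonally varying canopy density.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and that the classifier can untangle a depth-confounded signal of
realistic magnitude — not that any particular accuracy will be achieved on
real imagery, where the in-situ cartography itself is imperfect.

Under these defaults the trained classifier reaches high validation
accuracy shallow and visibly lower accuracy in the 25–40 m stratum — the
same qualitative depth pattern expected from optical detectability — and
that pattern, not any specific percentage, is what the end-to-end test
asserts.

## Numerical and design notes

* Rasters are plain-text ESRI ASCII grids (single band) or a JSON manifest
  plus one grid per band (multi-band); the NODATA value carries the
  validity mask and the header carries the georeference. Values are
  written with 17 significant digits, so write→read round-trips are
  bit-exact and identically configured pipeline runs are byte-identical
  (verified by MD5 in the run manifest).
* All inputs must already share one CRS and grid alignment; misalignment
  is a loud error, reprojection is upstream of this package.
* The screen's robust z is 0 when all date means are equal (0/0 guarded),
  and infinite when the MAD is zero but a date deviates.
* Probabilities are clamped to (10⁻¹², 1 − 10⁻¹²) to keep the
  cross-entropy finite; classes are always exactly 0 or 1.
* Problem sizes in the test suite (16×16 oracle maps, 64–96 px pipeline
  fixtures, the 256×256 default scene for the end-to-end check) were
  chosen as the smallest scenes that exercise each property with
  comfortable statistical margin.

## Known limitations

* The classifier is strictly pixel-wise; no convolutional context, no
  transfer learning. Cross-region application (train here, predict there)
  works as a usage pattern but carries the accuracy penalty any
  distribution shift implies.
* The sieve filter relabels in a single pass; a small component whose
  largest neighbour is itself small is resolved against original classes,
  not iterated to a fixed point.
* GeoJSON is the only vector format read; Shapefiles must be converted
  upstream.
* The automated screen is a proxy for expert visual inspection; its
  thresholds have no field calibration.
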