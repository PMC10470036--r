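---
title: "Plot-level canopy traits from UAV rasters: methods and design"
author: "uavpheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plot-level canopy traits from UAV rasters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uavpheno)
```

## The problem

Breeding trials of ridge-tilled row crops — the package was developed for
potato — need per-plot growth traits over the season: canopy height,
canopy volume, ground coverage, and vegetation indices. UAV photogrammetry
delivers the raw material as two georeferenced raster products per flight:
a digital surface model (DSM, the altitude of whatever surface the camera
saw, soil or canopy, in metres) and per-band reflectance maps. `uavpheno`
turns these, plus plot polygons and a vegetation mask, into a per-plot
trait table, and provides a synthetic field with closed-form ground truth
so the effect of flight altitude (hence ground sampling distance, GSD) on
trait precision can be quantified without a field campaign.

## The estimation procedure

**Base plane.** Plant height needs a reference altitude per plot. On a
hilled field the natural reference is the top of the ridges, estimated
once per season from a bare-soil flight shortly after planting: all DSM
values at pixel centres inside the plot polygon are sorted ascending and
the value at the 90% position is selected (nearest-rank, `ceiling(p*n)`,
1-based; no interpolation — the estimate is always an element of the
data). The rationale: furrow and flank pixels fill the lower ranks, and
reconstruction-noise spikes occupy the top ranks, so a selection just
below the top lands on the ridge-crest plateau whenever the flat crests
hold more than 10% of the plot's pixels. On flat soil with Gaussian
elevation noise the same rule estimates the 90th percentile of the noise,
soil + 1.2816 sd — a property the tests verify by simulation. The 90%
selection is implemented as an order statistic rather than an
interpolated quantile because a sorted-selection rule picks an element;
with 10^5 pixels per plot the difference is far below the 2 cm
georeferencing error of the input products either way. One scalar
altitude per plot is used (a horizontal plane, not a tilted fit), and the
selection runs over all plot pixels rather than crest pixels only — the
90% rule is precisely what makes the crest/furrow distinction
unnecessary.

**Height and volume.** For an acquisition date, the canopy height of a
masked vegetation pixel is `H = Z - zplane`, clipped below at zero
(negative differences are furrow pixels misclassified as vegetation or
elevation noise; without clipping they would produce negative volumes
early in the season). The plot's mean height averages `H` over masked
canopy pixels inside the polygon; its volume sums per-pixel columns
`gsd_x * gsd_y * H`, the pixel footprint being exactly the squared ground
sampling distance on the north-up, unrotated grids the package supports.
The two aggregates satisfy `volume = pixel_area * n_pixels * mean_height`
identically, which every pipeline run can assert at machine precision.

**Coverage.** The fraction of the plot polygon's area covered by
vegetation pixels: `(count of mask = 1 pixel centres inside) * pixel_area
/ polygon_area`. Pixel membership is decided by the pixel centre with a
half-open rule (south/west polygon edges inclusive), so zonal counts are
bit-reproducible and abutting plots never share a pixel. The coverage
statistic is not given an operational definition in much of the field
literature; the area-fraction definition here is the standard reading.

**Vegetation indices.** Five per-pixel formulas over the reflectance
bands: NDVI `(NIR-Red)/(NIR+Red)`, GNDVI `(NIR-Green)/(NIR+Green)`, NDRE
`(NIR-RedEdge)/(NIR+RedEdge)`, CIre `NIR/RedEdge - 1`, and LCI
`(NIR-RedEdge)/(NIR+Red)`. NDVI defaults to the red-band definition —
the standard one, and the one consistent with computing the index "from
the NIR and Red reflectance maps"; the green-band variant occasionally
listed under the NDVI name is exposed separately as GNDVI so either can
be selected deliberately. Zero denominators yield nodata, never
infinities, and the count of such pixels is attached to the index map.
Plot means average masked canopy pixels by default; a `mask_mode = "plot"`
switch averages all plot pixels instead, mimicking whole-plot proximal
sensors (e.g. a handheld GreenSeeker scan).

**Comparisons.** Trait series from two acquisitions (or UAV vs manual)
are compared by ordinary least squares: R² (squared Pearson correlation),
adjusted R² with the single-predictor formula `1-(1-R²)(n-1)/(n-2)`, RMSE
as the root mean squared residual in the trait's unit, and the two-sided
slope p-value (values below 10^-300 print as 0). R² is symmetric but
slope and intercept are not, so results record which series was the
predictor.

## The synthetic field

`scene_truth()` defines an analytic field whose defaults reproduce a
typical hilled potato trial: plots of 4.5 m x 2.25 m, ridges 0.30 m high
at 0.75 m spacing with a trapezoid cross-section (0.30 m flat crest,
0.15 m flat furrow bottom, linear flanks), plants at 0.30 m spacing on
the crests. The two survey GSDs are exactly 1/120 m and 1/60 m per pixel
(0.833 and 1.667 cm, the 15 m and 30 m flight altitudes of the
acquisition pair). Canopies are hemiellipsoids (or cuboids) with
closed-form volume, footprint and mean height, so the generator's
`$plot_truth` table is exact; canopy footprints may not overlap, keeping
the per-plot truth a plain sum. DSM sampling is point sampling at pixel
centres — the simplest convention consistent with gridded SfM products,
and the one that makes Riemann sums over grid-aligned cuboids exact. A
covered pixel's DSM value is the ridge-crest altitude plus the canopy
height function (the sensor sees the canopy surface, which stands on the
crest), so noise-free height maps reproduce the analytic canopy surface
with zero error. Elevation noise is i.i.d. Gaussian per pixel (default
sd 0.01 m, the order of the stated calibration error of RTK-georeferenced
reconstructions); the flat ridge crest was chosen over a sinusoid
precisely to give the base-plane rule an unambiguous target.

Two choices deserve emphasis:

* **Grid phase.** A real SfM raster's origin has arbitrary sub-pixel
  phase relative to the planting pattern, and two flights never share it.
  Because the trial's plant spacing is an exact multiple of both survey
  GSDs, anchoring the grid at the field origin would phase-lock every
  plant to the pixel lattice and turn discretisation error into a
  deterministic resonance — a configuration no real acquisition can
  produce. `grid_offset = "random"` (the default) therefore draws a
  seeded uniform sub-pixel origin shift per acquisition;
  `grid_offset = "none"` is available for the controlled grid-aligned
  experiments (cuboid exactness, matched-scene error bounds) where exact
  alignment is the point.
* **Pure spectra.** Band values are the pure leaf spectrum where the
  canopy covers the pixel centre and the pure soil spectrum elsewhere, so
  the mask, the bands and the truth are exactly consistent; this is what
  makes masked-mean NDVI provably identical across GSDs. A
  `mixed_pixels` switch linearly mixes boundary pixels by sub-pixel
  canopy fraction (3x3 subsampling) for users who want the harder
  segmentation setting; it is off by default.

What the generator does **not** emulate: spatially correlated SfM
artefacts (doming, melt around thin structures), radiometric variation
with sun angle and BRDF, mutual shading, plant-to-plant size variation
within a plot, and canopy movement between the two flights of a pair.
Passing tests therefore show that the estimation chain is correct and
that resolution effects have the expected direction and order of
magnitude on ideal reconstructions — not that field data of any quality
will reach the same accuracy.

## The two-altitude experiment

`gsd_experiment()` recreates the design of flying one field at two
altitudes: `n_scenes` paired acquisitions sample the same analytic
surfaces at both GSDs, with every plot of every scene given its own
canopy scale (the real trial pools varieties of different statures and
several dates into one regression) and a slightly varied leaf spectrum
per scene so indices vary. Base planes are estimated once per resolution
from a bare-ground scene, as a season does, and reused. Each trait is
then regressed coarse-on-fine and each resolution against truth.

The reproducible findings, verified by `tests/testthat/test-acceptance.R`
and recomputed by `scripts/acceptance.R`:

* grid-aligned cuboid canopies give identical, exact volumes at both
  GSDs (Riemann-sum exactness), so resolution effects are entirely a
  property of curved canopy boundaries and noise;
* noise-free hemiellipsoid recovery is better than 1% (volume) at
  0.833 cm/pixel and better than 3% at 1.667 cm/pixel for footprint
  radius 0.15 m, with the coarse error never below the fine error on
  matched scenes;
* masked-mean NDVI is identical across GSDs to machine precision, and
  pooled fine-vs-coarse NDVI regressions have R² = 1 — the
  reflectance-based index simply does not see the sampling density on
  unmixed pixels;
* across 20 independently seeded noisy experiments, the fine-GSD R²
  against truth is at least the coarse-GSD R² for height and volume
  (one-sided sign test, alpha 0.05) — the direction of the
  resolution effect on surface-derived traits.

### Problem sizes and numerical choices

Simulated experiments use 3-plot scenes, 6 scene pairs per experiment and
20 seeded replicates — sizes chosen so a regression has 18 paired points
and the sign test has conventional power, while a full test run stays in
the minutes range on one core. All lengths are metres internally; GSDs
quoted in cm/pixel are converted at the I/O boundary. Percentile
selection clamps its rank into `[1, n]`; translation equivariance and
permutation invariance of the base plane are exact, not approximate.
Pixel-in-cell lookups during resampling add a 1e-9-pixel epsilon before
flooring so that exact boundary coordinates do not flip cells under
floating-point round-off. Ties at a mask threshold classify as vegetation
(`>=`), which is what makes thresholded synthetic masks reproduce the
generator's truth mask pixel-for-pixel at any threshold strictly between
the soil and leaf index levels.

### File formats

Rasters are read and written as single-band ESRI ASCII grids (`.asc`,
plain text, understood by GDAL/QGIS/ArcGIS) with an optional `.prj`
sidecar carrying a projected-CRS identifier; geographic (degree) CRSs are
rejected because all internal lengths are metres, and the format is
north-up by construction so rotated geotransforms cannot occur. Plot
polygons travel as GeoJSON with configurable attribute names. Base
planes, trait tables and comparison reports are plain CSV; every CLI run
writes a JSON manifest (resolved options, package version, input/output
checksums) sufficient to reproduce it. Configuration files for the CLI
are YAML, with command-line flags taking precedence.

### Known limitations

The vegetation mask is an input: the package ships only an
index-threshold fallback, which is adequate on well-separated synthetic
spectra but is known to fail under field conditions (shadow, specular
soil, closed canopies) where a trained segmentation model is needed.
Reprojection between CRSs, tilted base planes, terrain models under
canopy, LAI or yield modelling are out of scope. Coverage can exceed 1 by
at most one boundary-pixel layer on very coarse grids, which is reported
as-is rather than clamped.
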