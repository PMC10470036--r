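# uavpheno

Plot-level crop trait extraction from UAV surface and reflectance
rasters, developed for ridge-tilled potato breeding trials.

UAV photogrammetry of a trial field yields a digital surface model (DSM,
surface altitude in metres) and per-band reflectance maps. `uavpheno`
turns these — plus plot polygons and a vegetation mask — into a per-plot
trait table:

* **Base plane.** Each plot's reference altitude `zplane_i` is estimated
  from a bare-soil survey by sorting the DSM values inside the plot and
  selecting the value at the 90% position (nearest-rank order statistic).
  On a hilled plot this lands on the flat ridge crest, below
  reconstruction-noise spikes and above furrow pixels.
* **Height.** Per masked vegetation pixel, `H_ij = Z_ij − zplane_i`,
  clipped below at 0; the plot trait is the mean over canopy pixels.
* **Volume.** `V_i = Σ_j gsd_x · gsd_y · H_ij` — each pixel contributes a
  column on its exact ground footprint, so
  `volume = pixel_area · n_pixels · mean_height` holds identically.
* **Coverage.** Canopy-pixel area over plot polygon area.
* **Vegetation indices.** NDVI `(NIR−Red)/(NIR+Red)`, GNDVI, NDRE
  `(NIR−RedEdge)/(NIR+RedEdge)`, CIre `NIR/RedEdge − 1`, LCI
  `(NIR−RedEdge)/(NIR+Red)`, averaged over masked canopy pixels (or the
  whole plot, for comparison with proximal sensors).
* **Comparisons.** OLS regression between trait series (coarse vs fine
  resolution, UAV vs manual): R², adjusted R², RMSE, slope p-value.

A synthetic-field generator with closed-form ground truth (ridged soil,
parametric hemiellipsoid/cuboid canopies, five-band spectra) makes the
central acquisition question — how ground sampling distance (0.833
cm/pixel at 15 m flight altitude vs 1.667 cm/pixel at 30 m) affects trait
precision — reproducible on a desktop. See the methods vignette
(`vignettes/uav-plot-phenotyping.Rmd`) for the model, assumptions and
design decisions.

## Worked example

```r
library(uavpheno)

truth  <- scene_truth(n_plots = 3, canopy_scale = c(0.6, 0.8, 1), seed = 42)
scene  <- make_scene(truth, gsd_pair()[["fine"]])          # 0.833 cm/pixel
bare   <- make_bareground_scene(truth, gsd_pair()[["fine"]])
planes <- estimate_base_planes(bare$dsm, bare$plots, source_date = "day10")
planes
#>   plot_id   zplane n_pixels percentile source_date
#> 1     P01 100.3068   145800        0.9       day10
#> 2     P02 100.3069   145800        0.9       day10
#> 3     P03 100.3069   145800        0.9       day10
```

The furrow bottom sits at 100 m and the ridges are 0.30 m tall, so the
selection recovers the ridge-crest altitude to about a millimetre under
1 cm elevation noise. Extracting the traits:

```r
records <- extract_traits(scene$dsm, scene$bands, scene$mask, scene$plots,
                          planes, date_label = "day60")
print(records[, c("plot_id", "variety", "mean_height", "volume", "coverage",
                  "ndvi", "ndre")], digits = 3)
#>   plot_id  variety mean_height volume coverage  ndvi  ndre
#> 1     P01 Euroviva       0.152  0.175    0.114 0.882 0.391
#> 2     P02    Etana       0.208  0.420    0.199 0.882 0.391
#> 3     P03   Priska       0.260  0.827    0.315 0.882 0.391
```

(The generator's closed-form truth for these plots is mean height
0.160/0.213/0.267 m and volume 0.183/0.434/0.848 m³; the small deficits
are the noise-induced upward bias of the base plane.) The two-altitude
simulation regresses every trait across resolutions and against truth:

```r
ex <- gsd_experiment(truth, n_scenes = 6, seed = 1)
ex
#> <gsd_experiment> 6 scene pair(s) at gsd 0.0083333 / 0.016667 m, seed 1
#>        trait      comparison  n      r2 adjusted_r2      rmse       p_value
#>  mean_height  coarse_vs_fine 18 0.99613     0.99588 2.985e-03  9.963270e-21
#>  mean_height   fine_vs_truth 18 0.99977     0.99976 7.378e-04  1.520213e-30
#>  mean_height coarse_vs_truth 18 0.99649     0.99627 2.842e-03  4.558829e-21
#>       volume  coarse_vs_fine 18 0.99995     0.99995 1.625e-03  4.454404e-36
#>       ...
#>         ndvi  coarse_vs_fine 18 1.00000     1.00000 6.243e-18 1.929847e-252
```

Height and volume track the truth more tightly at the finer GSD, while
masked-mean NDVI is identical across resolutions to machine precision —
the reflectance index does not see the sampling density.

## Command line

A thin launcher is installed with the package:

```sh
UAVPHENO=$(Rscript -e 'cat(system.file("exec/uavpheno", package = "uavpheno"))')
Rscript "$UAVPHENO" synth --seed 7 --out scene/        # synthetic scene to disk
Rscript "$UAVPHENO" baseplane --dsm bare/dsm.asc --plots bare/plots.geojson --out planes.csv
Rscript "$UAVPHENO" traits --dsm scene/dsm.asc --nir scene/band_nir.asc \
    --red scene/band_red.asc --rededge scene/band_rededge.asc \
    --mask scene/mask.asc --plots scene/plots.geojson \
    --planes planes.csv --out traits.csv
Rscript "$UAVPHENO" compare --x fine.csv --y coarse.csv --out stats.csv
Rscript "$UAVPHENO" gsd-experiment --seed 1 --out experiment/
```

Options can come from a YAML config (`--config run.yaml`; flags win), and
every run writes a JSON manifest with the resolved options and
input/output checksums.

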