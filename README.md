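# isomigrate

Stable-hydrogen isotope geographic assignment of migrant birds to natal
latitude, and a test for temporal migration patterns.

## The problem

Feathers grown on the natal grounds of a juvenile bird record the
stable-hydrogen isotope ratio (δ²H, in ‰) of local precipitation, which
declines roughly linearly with latitude across North America. Sampling
feathers from migrants at a stopover site therefore lets you ask where each
bird hatched — and whether birds from southern populations pass through
before birds from northern ones (a *type 1* temporal pattern) or after
(*type 2*).

`isomigrate` implements the full chain as composable R functions:

1. **Isoscape** — ordinary-least-squares regression of a gridded
   precipitation δ²H surface on temperature, elevation, latitude and
   longitude covariate grids, with a cellwise prediction-SE surface
   (`fit_isoscape()`, `predict_isoscape()`).
2. **Calibration** — a site-resampling bootstrap (default 1000 replicates)
   of the rescaling regression `feather δ²H ~ precipitation δ²H` over
   known-origin breeding populations; the precipitation isoscape is then
   converted cellwise to a feather isoscape
   `ŷ_b = ā + b̄·x_b` with an SD surface combining, in quadrature, the
   bootstrap intercept/slope/residual SDs and the isoscape prediction SE
   (`bootstrap_rescale()`, `convert_isoscape()`).
3. **Assignment** — for each bird with feather value `y*`, a normal
   likelihood per cell `b`,
   `L(b | y*) = φ(y*; μ_b, σ_b)`,
   masked to the species breeding range and normalized to unit total mass
   (`likelihood_surface()`); each surface is summarised by the
   probability-weighted centroid of its top 10% of cells, resampled to 100
   values (`centroid_top_fraction()`, `assign_cohort()`).
4. **Condition** — sex-specific fat-free mass from wing chord, fuel load =
   capture mass − fat-free mass, ordinal arrival day
   (`fat_free_mass()`, `fuel_load()`, `ordinal_day()`).
5. **Temporal model** — a generalized additive mixed model
   `centroid_lat ~ s(ordinal_day) + s(fat_free_mass) + s(fuel_load) +
   (1 | year)` via `mgcv`, with the arrival-day effect direction read from
   an OLS line through the fitted smooth; a significant positive effect is
   classified `type_1` (`fit_latitude_model()`, `classify_pattern()`).

A synthetic-data generator (`world_config()`, `make_world()`,
`make_calibration_sites()`, `make_migrants()`) produces every input with
known ground truth, so each stage is testable by parameter recovery.
Rasters are read and written as plain-text ESRI ASCII grids.

## Worked example

```r
library(isomigrate)
res <- run_pipeline(pipeline_config(outdir = "run1", seed = 7))
res$isoscape$model
#> <isoscape_model> 4 covariates, 2400 cells, R^2 = 0.9681, residual SD = 2.989 permil
res$rescale
#> <rescale_model> feather = -23.745 + 1.0526 x precip (1000 bootstrap replicates)
#>   intercept SD 3.870, slope SD 0.0800, mean residual SD 4.235 permil
res$temporal_fit
#> <temporal_fit> n = 150, year random-intercept variance = 0.001108 deg^2
#>             term      edf            F    p_value direction
#>      ordinal_day 3.153340 127.72777068 0.00000000  positive
#>  fat_free_mass_g 1.000272   5.13736315 0.02490271  positive
#>      fuel_load_g 1.000481   0.08861482 0.76726435      flat
#> arrival-day effect: positive
res$classification
#> [1] "type_1"
```

Reading the output: the isoscape regression recovers the simulated
precipitation model almost exactly (R² ≈ 0.97); the bootstrap rescaling
slope ≈ 1.05 brackets the generating tissue slope of 1; and the arrival-day
smooth is strongly significant and positive — birds assigned to higher
natal latitudes arrive later, the type 1 signature. With this seed the
assigned centroid latitudes correlate with the true natal latitudes at
r = 0.93 (merge `run1/centroids.csv` with `run1/truth.csv`).

Every run writes its grids (`.asc`), tables (`.csv`), model files and a
`manifest.json` (parameters, derived stage seeds, output checksums) to
`outdir`; re-running with the same config and seed reproduces all
non-timing outputs bit-exactly. A thin command-line wrapper lives at
`inst/cli/isomigrate.R` (`run`, `simulate`, `raster-info` subcommands).

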