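---
title: "Feather-deuterium assignment of migrants to natal latitude: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feather-deuterium assignment: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomigrate)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters, and the choices made
where the design was genuinely open. Nothing stated here as an empirical
result goes beyond what the test suite and `scripts/acceptance.R` compute.

## The assignment model

Growing-season precipitation δ²H declines approximately linearly with
latitude across North America, and the feathers a juvenile bird grows at
its natal site inherit that signal through a roughly linear tissue
transfer. The pipeline exploits this in four steps.

**Isoscape.** The precipitation surface is modelled by ordinary least
squares on four covariate grids — temperature, elevation, latitude,
longitude — over all jointly valid cells:
$x_b = \beta_0 + \beta^\top c_b + \varepsilon_b$. The fit assumes the
residual field is independent across cells; no geostatistical (kriging)
variant is provided, because the intended use case is a regression
isoscape on a single continental grid where spatial autocorrelation of the
residuals is weak. `predict_isoscape()` returns the cellwise fitted mean
and its design-based standard error
$\mathrm{se}(\hat x_b) = \hat\sigma\sqrt{c_b^\top (C^\top C)^{-1} c_b}$,
which is smallest at the covariate centroid — a property the tests check
against the closed form.

**Calibration.** Known-origin breeding populations supply per-site feather
means, SDs and sample sizes. Each of `n_boot = 1000` bootstrap replicates
draws one feather value per site from
$\mathcal N(\bar y_s, s_s)$ and one environmental value from
$\mathcal N(x_s, \mathrm{se}_s)$ — the environmental SD is the isoscape
prediction SE at the site, zero when unavailable — and fits
`feather ~ env` by unweighted OLS. The rescale model keeps the empirical
mean and SD of intercept, slope and residual SD across replicates.
Interpretation choices, flagged as such:

* replicates resample *values within sites* (one draw per site per
  replicate), not sites with replacement;
* a single-bird site (SD unreported) contributes its mean with no
  feather-side noise, with a logged warning;
* per-replicate regressions are unweighted by default; a
  weight-by-site-sample-size variant sits behind `weight_by_n = TRUE`.

**Conversion and per-bird surfaces.** The feather isoscape is
$\mu_b = \bar a + \bar b\, x_b$ with SD combined in quadrature —
$\sigma_b^2 = s_a^2 + (s_b |x_b|)^2 + \bar s_e^2 + (\bar b\,
\mathrm{se}(x_b))^2$ — assuming independence of the rescaling and isoscape
uncertainties; the serialized model file records this convention. Each
bird's surface is the normal likelihood $\varphi(y^*; \mu_b, \sigma_b)$
per cell, computed in log space with max-subtraction before
exponentiation so steep surfaces on large grids cannot underflow, masked
to the breeding range, and normalized to **unit total mass** (the
alternative, rescaling to max = 1, changes nothing downstream of the
centroid but would break the sum-to-one invariants the tests assert).
Cells with $\sigma_b = 0$ are rejected at input validation rather than
floored: a zero-SD cell is a modelling error, not a numerical one.

**Centroid.** Cells are ranked per bird; the top
$\lceil 0.10 \times n_\text{valid}\rceil$ are retained and resampled to
100 draws — uniformly, with replacement only when fewer than 100 cells are
retained — and the centroid is the probability-weighted mean of the drawn
cells' centre coordinates. "Top 10%" is read per bird's surface, not
pooled across birds, matching per-bird centroid production. A
probability-weighted draw is available via `weighted_draw = TRUE`. The
centroid is computed in plain lat/lon; at mid-latitudes on a sub-continental
window the great-circle correction is second-order relative to the
assignment uncertainty itself.

**Temporal model.** The additive mixed model is
`centroid_lat ~ s(ordinal_day, k = 5) + s(fat_free_mass, k = 5) +
s(fuel_load, k = 5) + s(year, bs = "re")`, fitted by REML in `mgcv`. The
year term is a random *intercept*; random slopes are out of scope. The
direction of a smooth is the sign of the slope of an OLS line through the
fitted smooth across the observed predictor range — robust to mild
non-linearity and invariant to affine rescaling of the predictor. A
significant (α = 0.05) positive arrival-day effect on natal latitude is
classified `type_1`, a significant negative one `type_2`, anything else
`indeterminate`. With a single observed year the model drops the random
term with a notice; a constant response short-circuits to a flat,
indeterminate fit.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_boot` | 1000 | replicates | study-procedure constant |
| `top_fraction` | 0.10 | proportion of valid cells | study-procedure constant |
| `n_resample` | 100 | draws | study-procedure constant |
| `alpha` | 0.05 | — | conventional test size |
| `resolution` | 0.5 | degrees/cell | no authoritative value exists; 0.5° gives a 60 × 40 grid that resolves the 30–50° N assignment band at ~40 cells of latitude while keeping a full run near a second |
| smooth basis `k` | 5 | — | adequate flexibility at n = 150 without overfitting |
| chord plausibility window | 30–60 | mm | brackets realistic hummingbird wing chords; out-of-window values warn but compute |

## What the generator emulates — and what it does not

`make_world()` builds temperature (linear latitudinal trend + smoothed
noise), elevation (smoothed Gaussian random field, clipped at zero — the
smoothing keeps the covariate matrix full rank), latitude and longitude
grids, and composes the precipitation surface from the configured linear
model (default latitudinal gradient −1.5 ‰/°, residual SD 3 ‰).
`make_calibration_sites()` places 10 populations (186 birds split as
evenly as possible) uniformly over the range mask.
`make_migrants()` draws natal cells uniformly over the mask (no natal
density gradient; a latitude-weighted hook can be added through the mask
itself), sets arrival day as `180 + 2 × natal_lat + N(0, 5)` days,
**redrawing** out-of-window arrivals rather than truncating them —
truncation would pile mass at the window edges and bias the
arrival~latitude slope the end-to-end test recovers. Dates are materialised
in each cohort year; ordinal-day handling is leap-aware for real dates.
Tissue transfer is slope 1, intercept −25 ‰, within-site SD 2 ‰; mass is
sex-specific fat-free mass (linear in wing chord) plus a Gamma(2, scale
0.25) fuel load, so fuel is nonnegative by construction.

The generator deliberately omits: realistic climatology, spatial
autocorrelation in the precipitation residuals, natal-density gradients,
sex or age effects on phenology, and measurement error on mass. Passing
the recovery tests therefore demonstrates that the *pipeline* is correct
and well calibrated under its own assumptions — not that those assumptions
hold for any particular field dataset.

## Numerical and engineering choices

* **Registration.** Cell-centre semantics everywhere; the origin is the
  outer corner of the first cell (ASCII-grid convention), rows north to
  south. Coordinate transforms round-trip exactly on integer indices.
* **Raster format.** Plain-text ESRI ASCII grid, written at 17
  significant digits so write/read round-trips are bit-exact. GeoTIFF is
  not supported in this build; `read_raster(format = "geotiff")` fails
  with a clear message. No reprojection: one geographic grid, WGS84
  assumed.
* **Extraction.** Containing-cell lookup, no interpolation — simpler,
  exactly testable, and consistent with the grid being the model's native
  support.
* **Nodata.** The sentinel is converted to `NA` internally and propagates
  through all arithmetic; masking never alters an in-range cell.
* **Seeds.** Every stochastic stage takes a seed derived from the master
  seed and a stage/bird label through a plain 31-bit polynomial string
  hash, so any stage or any single bird can be re-run in isolation and
  the whole run reproduces bit-exactly. The manifest records the derived
  seeds and MD5 checksums of every output.
* **Configuration.** Pipeline configs are YAML (`read_run_config()`),
  with every procedure constant surfaced as a named parameter and
  validated against the known field list.
* **Degenerate inputs.** All-zero masks, all-identical environmental
  values, fewer than 3 calibration sites, σ = 0 cells, single-year
  cohorts and constant responses all fail fast with named errors or fall
  back with logged notices, as exercised in the tests.

## Problem sizes used by the test suite

Module tests run on a 30 × 20 (1°) world; isoscape CI calibration uses
100 worlds at 2°; the end-to-end pattern-detection check runs 25 replicate
cohorts (n = 150 each) at the default 60 × 40 grid with generating
phenology slope +2 d/° and 25 under the null, asserting ≥ 80% and ≤ 10%
type-1 calls respectively. These sizes were chosen so the recovery
statistics are well inside their asymptotic regimes while a full suite run
stays around a minute.

## Known limitations

* The regression isoscape ignores residual spatial structure; assignment
  SDs are therefore mildly optimistic where residuals are autocorrelated.
* Fat-free-mass coefficients are a required input; the package never
  invents published regression coefficients, and the synthetic generator's
  values are ground truth only for its own worlds.
* Centroids shrink toward the range-mask centroid when surfaces are
  diffuse; the recovery correlation, not unbiasedness of the centroid, is
  the supported property.
* The F-statistics reported for smooth terms are `mgcv`'s standard
  approximate tests; exotic degrees-of-freedom conventions from other
  software are not reproduced.
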