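---
title: "Methods: fuzzy niche suitability under downscaled paleoclimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fuzzy niche suitability under downscaled paleoclimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleosuit)
```

## The model in one page

`paleosuit` chains five stages. A coarse monthly climate cube
(temperature in °C, precipitation in mm/month) is summarized into
20-year **snapshots** — long enough to smooth interannual noise, short
enough to match the horizon over which farming communities perceive and
adapt to climate. Each snapshot is **downscaled** by the delta method:
the coarse anomaly (snapshot minus a baseline window) is bilinearly
interpolated and added to a fine reference climatology, so all
fine-scale structure comes from the reference and all temporal change
from the simulation. A **fuzzy niche model** then scores each cell and
crop: every parameter has a trapezoidal membership built from an
absolute range $[a_{min}, a_{max}]$ and an optimal range
$[o_{min}, o_{max}]$; a candidate growing window is scored by the *law
of the minimum* (the weakest parameter decides), and the cell takes the
best of the 12 start months. Crop maps are combined into a **hybrid
rotation model** after trimming marginal values, and temporal change is
summarized by class-share differences, per-cell coefficients of
variation, and counts of binary suitability flips. Finally the
simulated regional series is **validated** against proxy
reconstructions with dynamic time warping (DTW) on z-scores, which
tolerates the lags and stretches that separate ecological archives from
forcing-driven simulations.

## Assumptions

* Monthly climatology is sufficient: no daily extremes, no phenology,
  no CO~2~ effects, no irrigation. Suitability is a climatic-edaphic
  envelope statement, not a yield prediction.
* The delta method assumes the fine spatial pattern of climate is
  stationary in time; only the coarse anomaly moves. Both variables use
  *additive* anomalies by default (a multiplicative precipitation mode
  exists behind `precip_method = "ratio"`), with negative precipitation
  clamped to 0.
* Static grids (terrain, soil) do not evolve across snapshots.
* No-data propagates as `NA`, never as 0 — a 0 is a statement
  ("unsuitable"), not a gap.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| snapshot window | 20 | years | agricultural adaptation horizon; one generation |
| trim threshold | 0.20 (strict >) | suitability | keeps near-unsuitable cells from inflating the hybrid mean |
| similarity threshold | 0.70 (strict >) | index | analogue quality floor for proxy record selection |
| dating density | > 5 | samples/window | rejects poorly dated archives |
| moving average | 20 | years | matches the snapshot scale in phase plots |
| class edges | 20/40/60/80 | % | fixed, global: class shares comparable across crops and snapshots |
| step pattern | `rj6c` | — | slope-constrained (2/3..3/2), query-normalizable |
| aggregator | mean of trimmed | — | see "Open choices" |

Crop parameters are trapezoids per niche parameter plus a growing-period
duration in whole months (monthly pipeline; day-based growing periods
must be rounded by the parameter author) and a three-class texture
table. An optional kill temperature (off by default) annuls any window
containing a month below it.

## What the synthetic world emulates — and what it does not

The generator produces, from one seed: Gaussian-smoothed terrain with a
broad ridge; slope from finite differences; TWI, wind exposure and
monthly radiation as autocorrelated fields conditioned on the organized
relief; soils by log-ratio closure (sand+silt+clay = 100 exactly) with
clay accumulating in wet cells; a climate cube whose fine truth is a
12-month climatology (seasonal cycle, meridional gradient, lapse rate
−6 °C/km, orographic gain +30 mm/km) modulated by a spatially uniform
regional anomaly — linear trend plus AR(1) (stationary SD
`noise_sd_temp`, persistence `ar1_coef`) plus monthly noise for
temperature, and a mean-one clamped log-normal factor for precipitation
whose SD in mm is `noise_sd_prec`; and proxy records that smooth, lag,
perturb and irregularly sample the regional series (exponential gaps,
i.e. Poisson-process dating). The first proxy record is anchored at the
reference site itself, emulating a local archive, so record selection
always has a candidate while the remaining random sites are genuinely
filtered.

Because the interannual anomaly is *spatially uniform*, the coarse cube
is exactly the block mean of the latent fine truth, and truth
climatologies per window are available in closed form — this is what
makes downscaling error measurable (and, for temperature, exactly
zero). Real ESM output has spatially structured interannual anomalies;
passing tests here validates the machinery, not the realism of any
specific simulation. Similarly, terrain conditioning of TWI/wind scales
with `1 − exp(−smoothing)`: white-noise micro-relief does not organize
drainage or exposure, so with the smoothing length at 0 the auxiliary
fields decorrelate from elevation — a deliberate design that keeps the
generator's statistical contract testable at both ends.

Default study conditions: a 10×10 coarse grid refined ×5 (50×50 fine
cells at 1 km), years −399..400 (astronomical numbering, year 0 = 1
BCE), five snapshot windows starting −309, −9, 100, 240, 340, labelled
half-open ("100–120 CE" = years 100..119; era-crossing labels print the
inclusive end year, "10 BCE–10 CE" = −9..10). Defaults
`ar1_coef = 0.7`, `noise_sd_temp = 0.8` °C, `noise_sd_prec = 10` mm,
trend 0.2 °C/century are realistic regional magnitudes for late-Holocene
variability; the proxy defaults (lag 10 a, smoothing 5 a, noise 0.3 z,
spacing 10 a) are typical of pollen-based reconstructions. Tests use
4×4 coarse worlds (20×20 fine) and 200–800-year series, sizes chosen so
the full suite exercises every stage in seconds.

## Numerical choices

* **Trapezoid edges**: membership at a degenerate edge
  (`amin == omin`) is 1 — the plateau wins. At a non-degenerate
  absolute edge membership is 0 (closed-out).
* **Texture translation**: clay ≤ 18 % is light, ≥ 35 % heavy, with
  ±5 %-wide linear transition bands; the three class degrees always sum
  to 1, and the membership is the degree-weighted mean of the crop's
  class suitabilities.
* **Classification**: left-closed bins on the percent scale
  (`[0,20) … [80,100]`), so 20 % is "low", 100 % is "very high".
* **Moving average**: centred; even windows half-weight the two extreme
  lags (so a linear series is unchanged in the interior); the window
  shrinks symmetrically at the edges.
* **z-scores**: sample SD over the baseline window (default: the whole
  analysis window); a constant series is an explicit error, not NaN.
* **Phase labels**: z ≥ 0 counts as warmer/wetter, making the four
  quadrant labels exhaustive and exclusive.
* **Bilinear downscaling**: coarse values are point values at cell
  centres; one replicated node is padded per side before interpolation,
  so edges see no extrapolation. With an odd refinement factor the
  coarse centres coincide with fine cells, giving exact nodal
  consistency; the default factor is 5.
* **Similarity index**: $\exp(-\sqrt{D/12})$ with $D$ the
  variance-normalized squared monthly distance (optionally minimized
  over the 12 seasonal rotations); variable-months with zero across-grid
  SD are dropped with a warning. The exponential-of-RMS form is this
  package's choice — it maps $D = 0$ to exactly 1 and is insensitive to
  the number of retained terms.
* **DTW**: local cost |Δz|; accumulation starts from the (1,1) cost;
  both endpoints anchored; ties broken toward the diagonal production;
  slope-infeasible pattern/length combinations raise an explicit error.
  The Rabiner–Juang family is built from a production table shipped as
  package data (`inst/extdata/rabiner_juang_types.yaml`) with slope
  weightings a–d applied per elementary move; the table is data, not
  code, so it can be corrected without touching the algorithm. Distances
  are verified against exhaustive monotone-path enumeration in the test
  suite.
* **CV maps**: sample (n−1) SD over snapshots divided by the mean, in
  percent, computed on values (not classes); mean-zero cells are
  no-data.

## Open choices made here

* **Hybrid aggregator**: the mean of trimmed values (trimmed cells
  count as 0) is the default — it matches the trim's stated purpose of
  preventing marginal areas from being overrepresented. A strict `min`
  and a `count-fraction` aggregator are selectable, since a stricter
  reading ("no suitability unless several crops pass") is also
  coherent.
* **Binary hybrid**: thresholds the hybrid value (strict >), mirroring
  the trim, rather than requiring all crops to pass.
* **Baseline window for anomalies**: the final 20 years of the cube,
  which double as the reference climatology's window — the coarse
  baseline and the fine reference then describe the same climate state,
  making the delta identity exact at zero anomaly.
* **Proxy compositing**: records are interpolated to the annual grid,
  averaged, then z-scored (composite-then-standardize); temperature and
  precipitation are aligned separately.
* **Distance units**: DTW distances on z-scores are reported in z-units
  alongside a rescaled value (z × the simulation series' SD), flagged
  as a unit-conversion convenience rather than a calibrated physical
  distance.

## Limitations

Suitability is relative to the supplied tolerance tables; with
synthetic crops the outputs validate mechanics, not agronomy. The
delta method cannot create fine-scale *change* (only fine-scale
*state*), the niche model ignores inter-annual failure risk inside a
snapshot, and DTW distances carry no significance test. Real tolerance
tables can be supplied verbatim as YAML (`read_crops_yaml()`), and real
climate/terrain grids can enter through the NetCDF readers, but CRS
handling is deliberately minimal: grids must already be aligned, and
the package refuses to resample implicitly.
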