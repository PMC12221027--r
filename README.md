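# paleosuit

Agroclimatic cultivation-suitability modelling under simulated past
climates.

`paleosuit` is for researchers who want to ask: *given a coarse
paleoclimate simulation, which parts of a landscape could have supported
which crops, and how did that change through time?* It implements the
full chain from raw simulated climate to interpretable suitability
products:

1. **Snapshot construction** — 20-year windows of a monthly climate cube
   are averaged into quasi-stationary climate states.
2. **Delta-method downscaling** — the coarse anomaly of each snapshot
   against a baseline window is interpolated bilinearly (over a padded
   domain) and *added* to a fine-resolution reference climatology:
   `fine = reference + interp(snapshot − baseline)`, with precipitation
   clamped at 0.
3. **Fuzzy niche scoring** — each crop carries trapezoidal tolerance
   ranges `(amin, omin, omax, amax)` per parameter: membership is 0
   outside the absolute range, 1 inside the optimal range, linear on the
   ramps. A growing window starting in month *s* scores
   `min` over all parameters (law of the minimum): monthly mean
   temperature, cumulative window precipitation, monthly solar
   radiation, slope, TWI, wind exposure, pH and soil texture. Cell
   suitability is the `max` over the 12 candidate start months, then
   classified into five fixed classes (very low … very high at
   20/40/60/80 %).
4. **Hybrid rotation model** — per-crop maps are trimmed (values ≤ 20 %
   set to 0) and aggregated (mean by default) into one
   rotation-suitability surface, with areal class shares, percentage-
   point changes between snapshots, per-cell coefficients of variation,
   and binary-hybrid change counts.
5. **Proxy validation** — simulated regional series are compared against
   proxy reconstructions (selected by a climate-similarity index > 0.7
   and dating density > 5) via dynamic time warping with configurable
   step patterns, including the Rabiner–Juang family (type VI, slope
   weighting c, by default).

A synthetic-world generator produces every input — terrain, soils, an
ESM-like climate cube with seasonal cycle, AR(1) variability and secular
trend, a fine reference climatology with elevation-driven structure, and
lagged/smoothed/noisy proxy records — so the whole pipeline is testable
offline with known ground truth.

## Worked example

```r
library(paleosuit)

spec     <- world_spec(seed = 1)                  # 30 x 30 km synthetic world
terrain  <- generate_terrain(spec)
soil     <- generate_soil(spec, terrain)
statics  <- static_grids(terrain, soil)
climate  <- generate_climate(spec, terrain,
                             snapshot_starts = c(-309, -9, 100, 240, 340))

## downscale the "310-290 BCE" snapshot onto the reference climatology
baseline <- snapshot_mean(climate$cube, climate$baseline_window[1])
snap <- delta_downscale(snapshot_mean(climate$cube, -309),
                        baseline, climate$reference)

## six synthetic crops -> hybrid rotation model
crops  <- generate_crops(6, seed = spec$seed)
maps   <- lapply(crops, function(cr) crop_suitability(snap, statics, cr))
hybrid <- hybrid_combine(maps)
round(class_area_shares(hybrid$classes), 3)
#>  very low       low  moderate      high very high
#>     0.430     0.331     0.226     0.013     0.000

## validate the simulation against synthetic proxy archives
sim     <- similarity_index(climate$reference, c(16, 16))
records <- generate_proxy(spec, climate$cube)
compare_simulation_proxy(climate$cube, records, sim,
                         pattern = "rj6c", window = c(-399, 400))
#> <ps_validation_report: 1 records, 784 years>
#>   temperature   dtw distance 417.382 (normalized 0.532), offset 9
#>   precipitation dtw distance 581.839 (normalized 0.742), offset 11
#>   phase agreement 34.8%
```

43 % of the landscape is nearly unsuitable for the rotation under this
snapshot, a quarter moderately suitable; one proxy archive passed the
similarity/dating selection, and its warping path sits ~9–11 years off
the diagonal — consistent with this world's built-in 10-year proxy
response lag.

The same pipeline runs from the shell:

```sh
Rscript exec/paleosuit run-all --seed 1 --out out/
```

writing NetCDF grids (downscaled snapshots, per-crop and hybrid
suitability, CV and change maps), CSV tables (class shares, changes,
annual phase series), crop YAML and a JSON validation report plus a
manifest with MD5 digests of every product.

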