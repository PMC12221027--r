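## Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

small_spec <- function(seed = 7) {
  world_spec(seed = seed, coarse_shape = c(4, 4), fine_factor = 5,
             year_range = c(-199, 100))
}

## a fully generated small world (terrain, soil, statics, climate, snapshot)
small_world <- function(seed = 7) {
  key <- paste0("w", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  spec <- small_spec(seed)
  terrain <- generate_terrain(spec)
  soil <- generate_soil(spec, terrain)
  statics <- static_grids(terrain, soil)
  climate <- generate_climate(spec, terrain, snapshot_starts = c(-149, -49, 50))
  baseline <- snapshot_mean(climate$cube, climate$baseline_window[1])
  snapshot <- delta_downscale(snapshot_mean(climate$cube, -149),
                              baseline, climate$reference)
  w <- list(spec = spec, terrain = terrain, soil = soil, statics = statics,
            climate = climate, baseline = baseline, snapshot = snapshot)
  .fixture_cache[[key]] <- w
  w
}

## hand-buildable flat climatology: every month the same values
constant_climatology <- function(temp, prec, nr = 4, nc = 4, cellsize = 1) {
  g <- ps_geom(nr, nc, cellsize = cellsize)
  climatology(array(temp, c(nr, nc, 12)), array(prec, c(nr, nc, 12)), g)
}

## statics that are optimal for almost any crop (flat, neutral soil)
neutral_statics <- function(nr = 4, nc = 4) {
  g <- ps_geom(nr, nc)
  structure(list(slope = matrix(1, nr, nc), twi = matrix(8, nr, nc),
                 wind = matrix(0.5, nr, nc),
                 solar = array(170, c(nr, nc, 12)),
                 sand = matrix(40, nr, nc), silt = matrix(40, nr, nc),
                 clay = matrix(20, nr, nc), ph = matrix(6.8, nr, nc),
                 geom = g),
            class = "ps_statics")
}

## a permissive crop whose optimum covers the neutral statics
easy_crop <- function(duration = 3, temp = trapezoid(0, 5, 25, 35),
                      prec = trapezoid(0, 50, 500, 1000)) {
  crop_params("easy", duration,
              temperature = temp, precipitation = prec,
              slope = trapezoid(0, 0, 10, 30),
              twi = trapezoid(0, 2, 12, 20),
              wind = trapezoid(0, 0, 1, 2),
              solar = trapezoid(0, 50, 300, 400),
              ph = trapezoid(4, 5, 8, 9))
}
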