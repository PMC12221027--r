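#' Generate synthetic terrain grids
#'
#' Produces elevation, slope, topographic wetness index (TWI), wind
#' exposure and 12 monthly solar-radiation layers on the fine grid.
#' Elevation is a Gaussian-smoothed random field; slope is its finite-
#' difference gradient; TWI, wind exposure and radiation are independent
#' autocorrelated fields conditioned on the *organized* (smoothed) relief.
#' The conditioning strength scales with `1 - exp(-terrain_smoothing)`:
#' white-noise micro-relief does not organize drainage or exposure, so with
#' no smoothing the auxiliary fields are pure noise.
#'
#' @param spec `ps_world_spec`.
#' @return object of class `ps_terrain`: list of `elevation` (m), `slope`
#'   (degrees), `twi`, `wind` (exposure index), `solar` (rows x cols x 12,
#'   W/m2) and `geom`.
#' @export
generate_terrain <- function(spec) {
  validate_world_spec(spec)
  g <- fine_geom(spec)
  nr <- g$nrow; nc <- g$ncol
  sig <- spec$terrain_smoothing
  couple <- 1 - exp(-sig)    # relief organization -> conditioning strength

  with_seed(stage_seed(spec$seed, "terrain"), {
    relief <- noise_field(nr, nc, sig)
    ## broad west-east ridge so the domain has persistent structure
    ridge <- matrix(rep(sin(seq(0, pi, length.out = nc)), each = nr), nr, nc)
    elevation <- pmax(400 + 380 * relief + 350 * couple * ridge, 0)
    slope <- slope_from_elevation(elevation, g$cellsize * 1000)

    zrel <- if (stats::sd(elevation) > 0)
      (elevation - mean(elevation)) / stats::sd(elevation)
    else elevation * 0
    twi <- 8 + 2.5 * noise_field(nr, nc, sig) -
      couple * (1.2 * zrel + 0.12 * slope)
    wind <- 0.6 + 0.2 * noise_field(nr, nc, sig) + couple * 0.25 * zrel
    wind <- pmax(wind, 0)

    sol_noise <- noise_field(nr, nc, sig)
    solar <- array(0, dim = c(nr, nc, 12L))
    for (m in 1:12) {
      seasonal <- 170 + 110 * cos(2 * pi * (m - 6.5) / 12)
      solar[, , m] <- pmax(seasonal * (1 + 0.08 * sol_noise) -
                             couple * 0.4 * slope, 10)
    }
    structure(list(elevation = elevation, slope = slope, twi = twi,
                   wind = wind, solar = solar, geom = g),
              class = "ps_terrain")
  })
}

#' Slope (degrees) from an elevation field
#'
#' Central differences in the interior, one-sided at edges; a constant
#' elevation field yields exactly zero slope.
#'
#' @param elevation matrix, metres.
#' @param cellsize_m cell edge, metres.
#' @return matrix of slope angles in degrees.
#' @export
slope_from_elevation <- function(elevation, cellsize_m) {
  nr <- nrow(elevation); nc <- ncol(elevation)
  ddy <- elevation[pmin(seq_len(nr) + 1L, nr), , drop = FALSE] -
    elevation[pmax(seq_len(nr) - 1L, 1L), , drop = FALSE]
  dy <- ddy / (cellsize_m * ifelse(seq_len(nr) %in% c(1L, nr), 1, 2))
  ddx <- elevation[, pmin(seq_len(nc) + 1L, nc), drop = FALSE] -
    elevation[, pmax(seq_len(nc) - 1L, 1L), drop = FALSE]
  dx <- sweep(ddx, 2L,
              cellsize_m * ifelse(seq_len(nc) %in% c(1L, nc), 1, 2), "/")
  atan(sqrt(dx^2 + dy^2)) * 180 / pi
}

#' Generate synthetic soil grids
#'
#' Sand/silt/clay percentages (summing to 100 per cell) and pH, all
#' spatially autocorrelated; clay accumulates preferentially in wet,
#' low-slope cells when terrain is supplied.
#'
#' @param spec `ps_world_spec`.
#' @param terrain optional `ps_terrain` used to condition the texture.
#' @return object of class `ps_soil`: `sand`, `silt`, `clay` (percent),
#'   `ph`, and `geom`.
#' @export
generate_soil <- function(spec, terrain = NULL) {
  validate_world_spec(spec)
  g <- fine_geom(spec)
  nr <- g$nrow; nc <- g$ncol
  sig <- spec$terrain_smoothing
  with_seed(stage_seed(spec$seed, "soil"), {
    wet <- if (!is.null(terrain)) {
      tz <- terrain$twi
      (tz - mean(tz)) / max(stats::sd(tz), 1e-12)
    } else matrix(0, nr, nc)
    ## latent log-abundances, then closure to 100 %
    la_sand <- 1.1 + 0.45 * noise_field(nr, nc, sig) - 0.15 * wet
    la_silt <- 1.0 + 0.35 * noise_field(nr, nc, sig)
    la_clay <- 0.8 + 0.45 * noise_field(nr, nc, sig) + 0.30 * wet
    es <- exp(la_sand); ei <- exp(la_silt); ec <- exp(la_clay)
    tot <- es + ei + ec
    ph <- pmin(pmax(6.8 + 0.7 * noise_field(nr, nc, sig), 4.5), 9)
    structure(list(sand = 100 * es / tot, silt = 100 * ei / tot,
                   clay = 100 * ec / tot, ph = ph, geom = g),
              class = "ps_soil")
  })
}

#' Assemble the static (time-invariant) input grids of the niche model
#'
#' @param terrain `ps_terrain`.
#' @param soil `ps_soil` on the same grid.
#' @return object of class `ps_statics` holding slope, twi, wind, solar,
#'   sand, silt, clay, ph and the shared geometry.
#' @export
static_grids <- function(terrain, soil) {
  stop_if_misaligned(terrain$geom, soil$geom, "terrain", "soil")
  structure(list(slope = terrain$slope, twi = terrain$twi,
                 wind = terrain$wind, solar = terrain$solar,
                 sand = soil$sand, silt = soil$silt, clay = soil$clay,
                 ph = soil$ph, geom = terrain$geom),
            class = "ps_statics")
}
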