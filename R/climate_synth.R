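#' Construct a climate cube
#'
#' Monthly temperature and precipitation grids over a gap-free year range.
#'
#' @param years strictly increasing, gap-free integer years.
#' @param temperature,precipitation arrays `[year, month, row, col]`,
#'   degC and mm/month.
#' @param geom `ps_geom` of the grid.
#' @return object of class `ps_cube`.
#' @export
climate_cube <- function(years, temperature, precipitation, geom) {
  years <- as.integer(years)
  if (any(diff(years) != 1L)) stop("years must be strictly increasing and gap-free")
  dt <- dim(temperature); dp <- dim(precipitation)
  if (length(dt) != 4L || !identical(dt, dp))
    stop("temperature/precipitation must be [year, month, row, col] arrays of equal shape")
  if (dt[1] != length(years) || dt[2] != 12L)
    stop("cube needs one layer per year and exactly 12 months")
  if (dt[3] != geom$nrow || dt[4] != geom$ncol)
    stop("cube grid does not match its geometry")
  if (any(precipitation < 0, na.rm = TRUE))
    stop("precipitation must be >= 0 everywhere")
  structure(list(years = years, temperature = temperature,
                 precipitation = precipitation, geom = geom),
            class = "ps_cube")
}

#' @export
print.ps_cube <- function(x, ...) {
  cat(sprintf("<ps_cube %d years (%d..%d), grid %dx%d>\n",
              length(x$years), x$years[1], x$years[length(x$years)],
              x$geom$nrow, x$geom$ncol))
  invisible(x)
}

#' Construct a 12-month climatology
#' @param temperature,precipitation arrays `[row, col, 12]`.
#' @param geom `ps_geom`.
#' @param label window label, e.g. `"310-290 BCE"`.
#' @param window integer `c(start, end)` of the averaged years (inclusive).
#' @return object of class `ps_climatology`.
#' @export
climatology <- function(temperature, precipitation, geom,
                        label = "", window = c(NA_integer_, NA_integer_)) {
  stopifnot(identical(dim(temperature), dim(precipitation)),
            dim(temperature)[3] == 12L)
  if (any(precipitation < 0, na.rm = TRUE))
    stop("precipitation must be >= 0 everywhere")
  structure(list(label = label, window = as.integer(window),
                 temperature = temperature, precipitation = precipitation,
                 geom = geom),
            class = "ps_climatology")
}

## seasonal baselines of the synthetic Mediterranean-type regime
seasonal_temp <- function(m) 15 + 9 * cos(2 * pi * (m - 7) / 12)
seasonal_prec <- function(m) 65 + 45 * cos(2 * pi * (m - 1) / 12)

## AR(1) series with stationary SD `sd`
ar1_series <- function(n, phi, sd) {
  if (sd <= 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) for (t in 2:n) x[t] <- phi * x[t - 1] + stats::rnorm(1, 0, innov_sd)
  x
}

#' Generate the synthetic climate system
#'
#' Builds a latent fine-grid "truth": a 12-month fine climatology with
#' elevation-driven lapse/orographic structure, modulated year by year by a
#' regional anomaly (linear trend + AR(1) + monthly noise for temperature;
#' a clamped log-normal AR(1) factor for precipitation). The coarse cube is
#' the exact block mean of that truth; the reference climatology is the
#' truth averaged over a designated "modern" window (the final
#' `window_length` years, playing the observational-climatology role); and
#' the truth climatology of every requested snapshot window is retained so
#' downscaling error is measurable.
#'
#' @param spec `ps_world_spec`.
#' @param terrain `ps_terrain` on the spec's fine grid.
#' @param snapshot_starts integer vector of snapshot window start years
#'   (each window spans `[start, start + window_length)`).
#' @param window_length snapshot window length in years (default 20).
#' @return object of class `ps_world_climate`: `cube` (coarse `ps_cube`),
#'   `reference` (fine `ps_climatology`), `truth` (named list of fine
#'   `ps_climatology`, one per snapshot window plus the reference window),
#'   `baseline_window`, and the regional anomaly series used.
#' @export
generate_climate <- function(spec, terrain, snapshot_starts = integer(0),
                             window_length = 20L) {
  validate_world_spec(spec)
  gF <- fine_geom(spec)
  stop_if_misaligned(terrain$geom, gF, "terrain", "spec fine grid")
  years <- spec_years(spec)
  ny <- length(years)
  if (ny < window_length)
    stop("year_range shorter than one snapshot window")
  for (s in snapshot_starts)
    if (s < years[1] || s + window_length - 1L > years[ny])
      stop("snapshot window [", s, ", ", s + window_length, ") outside year range")

  f <- spec$fine_factor
  nrF <- gF$nrow; ncF <- gF$ncol

  ## fine 12-month climatology with lapse, orographic and meridional structure
  elev_km <- terrain$elevation / 1000
  lat <- matrix(rep(seq(1, -1, length.out = nrF), ncF), nrF, ncF)
  clim_t <- array(0, c(nrF, ncF, 12L))
  clim_p <- array(0, c(nrF, ncF, 12L))
  for (m in 1:12) {
    clim_t[, , m] <- seasonal_temp(m) + 1.5 * lat - spec$lapse_rate * elev_km
    clim_p[, , m] <- pmax(1, seasonal_prec(m) *
                            (1 + 0.1 * lat) + spec$prec_orographic_gain * elev_km)
  }

  ## regional anomaly series (spatially uniform by construction, so the
  ## coarse cube is exactly the block mean of the latent fine truth)
  with_seed(stage_seed(spec$seed, "climate"), {
    trend <- spec$trend_per_century * (years - years[1]) / 100
    v <- ar1_series(ny, spec$ar1_coef, spec$noise_sd_temp)
    w <- if (spec$noise_sd_temp > 0)
      matrix(stats::rnorm(ny * 12L, 0, 0.5 * spec$noise_sd_temp), ny, 12L)
    else matrix(0, ny, 12L)
    anom_t <- trend + v + w          # [year, month]

    mean_p <- mean(seasonal_prec(1:12))
    cv <- spec$noise_sd_prec / mean_p
    if (cv > 0) {
      u <- ar1_series(ny, spec$ar1_coef, 1)
      e <- matrix(stats::rnorm(ny * 12L), ny, 12L)
      z <- (u + e) / sqrt(2)
      sig <- sqrt(log(1 + cv^2))
      fac_p <- exp(sig * z - sig^2 / 2)   # mean-one log-normal factor
    } else fac_p <- matrix(1, ny, 12L)
  })

  ## coarse cube = block mean of the fine truth
  coarse_t_clim <- array(0, c(spec$coarse_shape[1], spec$coarse_shape[2], 12L))
  coarse_p_clim <- coarse_t_clim
  for (m in 1:12) {
    coarse_t_clim[, , m] <- block_mean(clim_t[, , m], f)
    coarse_p_clim[, , m] <- block_mean(clim_p[, , m], f)
  }
  nrC <- spec$coarse_shape[1]; ncC <- spec$coarse_shape[2]
  tempC <- array(0, c(ny, 12L, nrC, ncC))
  precC <- array(0, c(ny, 12L, nrC, ncC))
  for (m in 1:12) {
    tempC[, m, , ] <- outer(anom_t[, m], coarse_t_clim[, , m], "+")
    precC[, m, , ] <- outer(fac_p[, m], coarse_p_clim[, , m], "*")
  }
  precC <- pmax(precC, 0)
  cube <- climate_cube(years, tempC, precC, coarse_geom(spec))

  ## truth climatology over an arbitrary window of years
  truth_clim <- function(start, label) {
    idx <- which(years >= start & years < start + window_length)
    tw <- clim_t; pw <- clim_p
    for (m in 1:12) {
      tw[, , m] <- clim_t[, , m] + mean(anom_t[idx, m])
      pw[, , m] <- pmax(0, clim_p[, , m] * mean(fac_p[idx, m]))
    }
    climatology(tw, pw, gF, label = label,
                window = c(start, start + window_length - 1L))
  }

  ref_start <- years[ny] - window_length + 1L
  reference <- truth_clim(ref_start, "reference")
  truth <- list()
  for (s in snapshot_starts)
    truth[[window_label(s, window_length)]] <-
      truth_clim(s, window_label(s, window_length))

  structure(list(cube = cube, reference = reference, truth = truth,
                 baseline_window = c(ref_start, years[ny]),
                 anomaly_temperature = anom_t,
                 precipitation_factor = fac_p,
                 window_length = as.integer(window_length)),
            class = "ps_world_climate")
}

#' Human-readable label of a snapshot window
#'
#' Uses astronomical year numbering internally and BCE/CE for display:
#' start -309 with length 20 prints as "310-290 BCE".
#'
#' @param start first astronomical year of the window.
#' @param length_years window length.
#' @return character label.
#' @export
window_label <- function(start, length_years = 20L) {
  last <- start + length_years - 1L
  fmt <- function(y, era_of) {
    if (y <= 0) paste0(1 - y, if (era_of) " BCE" else "")
    else paste0(y, if (era_of) " CE" else "")
  }
  if (last <= 0) paste0(1 - start, "-", 1 - last - 1L, " BCE")
  else if (start > 0) paste0(start, "-", last + 1L, " CE")
  else paste0(1 - start, " BCE-", last, " CE")   # era-crossing: inclusive end
}
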