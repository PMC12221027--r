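#' Specification of a synthetic study region
#'
#' Bundles every knob of the synthetic-world generators: grid layout, year
#' range, the statistical structure of the simulated climate (trend, AR(1)
#' interannual persistence, noise), the elevation-climate couplings, and the
#' proxy-archive distortions (smoothing, lag, noise, irregular sampling).
#'
#' Years use astronomical numbering (year 0 = 1 BCE), so arithmetic is
#' continuous across the BCE/CE boundary; the label "310-290 BCE" denotes
#' the 20 years -309..-290.
#'
#' Defaults emulate a Mediterranean-type seasonal regime with modest
#' centennial drift, interannual persistence typical of regional temperature
#' series, and pollen-archive-like proxy distortion; see the methods
#' vignette for the reasoning behind each value.
#'
#' @param seed integer seed; all generators are deterministic given it.
#' @param coarse_shape integer `c(rows, cols)` of the coarse climate grid.
#' @param fine_factor odd integer refinement per axis (fine = coarse x factor).
#' @param year_range integer `c(first, last)` astronomical years, inclusive.
#' @param trend_per_century temperature drift, degC per century.
#' @param ar1_coef lag-1 autocorrelation of the interannual anomaly, in [0,1).
#' @param noise_sd_temp stationary SD of the interannual temperature
#'   anomaly, degC.
#' @param noise_sd_prec SD of regional monthly precipitation about its
#'   climatology, mm (applied as a clamped log-normal factor).
#' @param lapse_rate temperature decrease with elevation, degC per km.
#' @param prec_orographic_gain precipitation increase with elevation,
#'   mm per km.
#' @param proxy_lag ecological response lag of the proxy archive, years.
#' @param proxy_smoothing moving-average window the archive applies, years.
#' @param proxy_noise_sd proxy noise in z-units of the underlying series.
#' @param proxy_sample_spacing mean gap between dated samples, years.
#' @param terrain_smoothing Gaussian correlation length of the synthetic
#'   relief and auxiliary fields, in fine cells; 0 gives white-noise fields.
#' @return validated object of class `ps_world_spec`.
#' @export
world_spec <- function(seed = 1L,
                       coarse_shape = c(6L, 6L),
                       fine_factor = 5L,
                       year_range = c(-399L, 400L),
                       trend_per_century = 0.2,
                       ar1_coef = 0.7,
                       noise_sd_temp = 0.8,
                       noise_sd_prec = 10,
                       lapse_rate = 6.0,
                       prec_orographic_gain = 30,
                       proxy_lag = 10L,
                       proxy_smoothing = 5L,
                       proxy_noise_sd = 0.3,
                       proxy_sample_spacing = 10,
                       terrain_smoothing = 4) {
  spec <- structure(list(
    seed = as.integer(seed),
    coarse_shape = as.integer(coarse_shape),
    fine_factor = as.integer(fine_factor),
    year_range = as.integer(year_range),
    trend_per_century = trend_per_century,
    ar1_coef = ar1_coef,
    noise_sd_temp = noise_sd_temp,
    noise_sd_prec = noise_sd_prec,
    lapse_rate = lapse_rate,
    prec_orographic_gain = prec_orographic_gain,
    proxy_lag = as.integer(proxy_lag),
    proxy_smoothing = as.integer(proxy_smoothing),
    proxy_noise_sd = proxy_noise_sd,
    proxy_sample_spacing = proxy_sample_spacing,
    terrain_smoothing = terrain_smoothing
  ), class = "ps_world_spec")
  validate_world_spec(spec)
  spec
}

validate_world_spec <- function(spec) {
  with(spec, {
    if (length(coarse_shape) != 2L || any(coarse_shape < 2L))
      stop("coarse_shape must be two dimensions, each >= 2")
    if (fine_factor < 1L || fine_factor %% 2L == 0L)
      stop("fine_factor must be a positive odd integer")
    if (year_range[2] < year_range[1])
      stop("year_range must be non-empty")
    if (ar1_coef < 0 || ar1_coef >= 1)
      stop("ar1_coef must lie in [0, 1)")
    if (noise_sd_temp < 0 || noise_sd_prec < 0 || proxy_noise_sd < 0)
      stop("noise standard deviations must be >= 0")
    if (proxy_sample_spacing <= 0)
      stop("proxy_sample_spacing must be positive")
  })
  invisible(spec)
}

#' @export
print.ps_world_spec <- function(x, ...) {
  cat(sprintf(
    "<ps_world_spec seed %d: coarse %dx%d, fine x%d, years %d..%d>\n",
    x$seed, x$coarse_shape[1], x$coarse_shape[2], x$fine_factor,
    x$year_range[1], x$year_range[2]))
  invisible(x)
}

#' Coarse-grid geometry implied by a world spec
#' @param spec `ps_world_spec`.
#' @return `ps_geom` of the coarse grid (cellsize = fine_factor km).
#' @export
coarse_geom <- function(spec) {
  ps_geom(spec$coarse_shape[1], spec$coarse_shape[2],
          cellsize = spec$fine_factor)
}

#' Fine-grid geometry implied by a world spec
#' @param spec `ps_world_spec`.
#' @return `ps_geom` of the fine grid (1 km cells).
#' @export
fine_geom <- function(spec) refine_geom(coarse_geom(spec), spec$fine_factor)

#' All years covered by a world spec
#' @param spec `ps_world_spec`.
#' @return integer vector of astronomical years.
#' @export
spec_years <- function(spec) seq(spec$year_range[1], spec$year_range[2])
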