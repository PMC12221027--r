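#' Generate synthetic proxy climate records
#'
#' Emulates pollen-archive-style reconstructions: each record is the
#' regional annual climate series, smoothed with a centred moving average
#' (`proxy_smoothing` years), delayed by an ecological response lag
#' (`proxy_lag` years: the value dated to year y reflects the climate of
#' year y - lag), perturbed with noise (`proxy_noise_sd`, in z-units of
#' the smoothed series), and sampled at irregular years whose gaps are
#' exponentially distributed with mean `proxy_sample_spacing` (a Poisson
#' sampling process mimicking radiocarbon-dated depths).
#'
#' The first record is anchored at the fine-grid centre cell — the
#' pipeline's default reference site — emulating a local archive at the
#' study site; the remaining sites are placed uniformly at random, so
#' similarity-based selection genuinely filters them.
#'
#' @param spec `ps_world_spec`.
#' @param cube coarse `ps_cube` covering the spec's year range.
#' @param n_sites number of records to generate.
#' @return object of class `ps_proxy_records`: a list of records, each
#'   with `site_id`, `row`/`col` (fine-grid location), and `samples`
#'   (data.frame year/temperature/precipitation); the true lag is stored
#'   in attribute `true_lag` as ground truth for validation tests.
#' @export
generate_proxy <- function(spec, cube, n_sites = 8L) {
  validate_world_spec(spec)
  years <- spec_years(spec)
  if (!all(years %in% cube$years)) stop("cube does not cover the spec's year range")
  if (spec$proxy_lag > length(years) / 2)
    stop("proxy_lag larger than half the series length")

  region <- cbind(row = rep(seq_len(cube$geom$nrow), cube$geom$ncol),
                  col = rep(seq_len(cube$geom$ncol), each = cube$geom$nrow))
  ann <- annual_aggregate(cube, region)
  sm_t <- moving_average(ann$temperature, spec$proxy_smoothing)
  sm_p <- moving_average(ann$precipitation, spec$proxy_smoothing)

  gF <- fine_geom(spec)
  lag <- spec$proxy_lag
  with_seed(stage_seed(spec$seed, "proxy"), {
    records <- vector("list", n_sites)
    for (s in seq_len(n_sites)) {
      ## irregular sample years (exponential gaps, mean spacing)
      yr_min <- years[1] + lag
      gaps <- stats::rexp(ceiling(2 * diff(range(years)) /
                                    spec$proxy_sample_spacing) + 10L,
                          rate = 1 / spec$proxy_sample_spacing)
      yrs <- yr_min + cumsum(gaps)
      yrs <- unique(floor(yrs[yrs <= years[length(years)]]))
      if (length(yrs) < 2L) yrs <- c(yr_min, years[length(years)])
      idx <- match(yrs - lag, ann$year)     # lagged source years
      tv <- sm_t[idx]; pv <- sm_p[idx]
      if (spec$proxy_noise_sd > 0) {
        tv <- tv + stats::rnorm(length(tv), 0,
                                spec$proxy_noise_sd * stats::sd(sm_t))
        pv <- pv + stats::rnorm(length(pv), 0,
                                spec$proxy_noise_sd * stats::sd(sm_p))
      }
      loc <- if (s == 1L)
        c(gF$nrow %/% 2L + 1L, gF$ncol %/% 2L + 1L)   # local archive
      else c(sample.int(gF$nrow, 1L), sample.int(gF$ncol, 1L))
      records[[s]] <- list(
        site_id = sprintf("site%02d", s),
        row = loc[1], col = loc[2],
        samples = data.frame(year = as.integer(yrs),
                             temperature = tv, precipitation = pv))
    }
  })
  structure(records, class = "ps_proxy_records", true_lag = lag)
}

#' Number of dated samples a record holds inside a year window
#' @param record one element of a `ps_proxy_records` list.
#' @param window integer `c(first, last)` years, inclusive.
#' @return integer count.
#' @export
dating_count <- function(record, window) {
  sum(record$samples$year >= window[1] & record$samples$year <= window[2])
}
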