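#' Select proxy records by climate similarity and dating density
#'
#' Keeps records whose site similarity is strictly above
#' `min_similarity` and whose number of dated samples inside the
#' analysis window is strictly above `min_dates`. Records outside the
#' similarity map's extent are excluded with a warning.
#'
#' @param records `ps_proxy_records`.
#' @param similarity `ps_similarity` covering the record locations.
#' @param min_similarity strict similarity threshold (default 0.7).
#' @param min_dates strict dated-sample threshold (default 5).
#' @param window integer `c(first, last)` years of the analysis window.
#' @return `ps_proxy_records` subset (possibly empty).
#' @export
select_records <- function(records, similarity, min_similarity = 0.7,
                           min_dates = 5L, window) {
  keep <- logical(length(records))
  for (k in seq_along(records)) {
    rec <- records[[k]]
    if (rec$row < 1 || rec$row > similarity$geom$nrow ||
          rec$col < 1 || rec$col > similarity$geom$ncol) {
      warning("record ", rec$site_id,
              " outside the similarity map extent; excluded")
      next
    }
    sim <- similarity$values[rec$row, rec$col]
    keep[k] <- sim > min_similarity && dating_count(rec, window) > min_dates
  }
  structure(records[keep], class = "ps_proxy_records",
            true_lag = attr(records, "true_lag"))
}

#' Linearly interpolate a proxy record onto target years
#'
#' Piecewise-linear interpolation through the dated samples; target
#' years outside the record's span are dropped (never extrapolated) and
#' reported in the `dropped_years` attribute with a warning.
#'
#' @param record one proxy record (with a `samples` data.frame).
#' @param target_years integer years wanted.
#' @return data.frame `year`, `temperature`, `precipitation`, with
#'   attribute `dropped_years`.
#' @export
interpolate_record <- function(record, target_years) {
  s <- record$samples
  if (nrow(s) < 2L)
    stop("record ", record$site_id,
         " has a single sample; interpolation is underdetermined")
  if (any(diff(s$year) <= 0)) stop("sample years must be strictly increasing")
  inside <- target_years >= s$year[1] & target_years <= s$year[nrow(s)]
  dropped <- target_years[!inside]
  if (length(dropped) > 0L)
    warning("record ", record$site_id, ": ", length(dropped),
            " target years outside the sample span were dropped")
  yrs <- target_years[inside]
  out <- data.frame(
    year = yrs,
    temperature = stats::approx(s$year, s$temperature, yrs)$y,
    precipitation = stats::approx(s$year, s$precipitation, yrs)$y)
  attr(out, "dropped_years") <- dropped
  out
}

#' Average several annual series on a common year grid
#'
#' @param series_list list of >= 1 data.frames with `year` and value
#'   columns; all must share the identical year vector.
#' @return data.frame of per-year unweighted means.
#' @export
composite_series <- function(series_list) {
  if (length(series_list) < 1L) stop("need at least one series")
  yrs <- series_list[[1]]$year
  for (s in series_list[-1])
    if (!identical(s$year, yrs))
      stop("series are not on a common year grid")
  vars <- setdiff(names(series_list[[1]]), "year")
  out <- data.frame(year = yrs)
  for (v in vars)
    out[[v]] <- rowMeans(sapply(series_list, function(s) s[[v]]))
  out
}

#' Compare a climate simulation against proxy reconstructions
#'
#' The full validation pipeline: select records by similarity and dating
#' density, interpolate each to the annual grid of the analysis window,
#' composite them, z-score both the composite and the simulated regional
#' series over the common years, and align per variable by dynamic time
#' warping. Also tabulates the fraction of years whose climate-phase
#' label (quadrant of the z-score signs) agrees between simulation and
#' proxy, and a rescaled distance (z-distance times the simulation
#' baseline SD, flagged as a unit-conversion convenience).
#'
#' @param cube coarse `ps_cube`.
#' @param records `ps_proxy_records`.
#' @param similarity `ps_similarity`.
#' @param pattern step pattern or name (default `"rj6c"`).
#' @param window analysis window `c(first, last)` years.
#' @param region coarse cells to average the simulation over (default
#'   the central 2x2 block, mirroring the four surrounding cells of a
#'   site at a grid-corner intersection).
#' @param min_similarity,min_dates selection thresholds.
#' @param smooth_years optional moving-average window applied to the
#'   simulated series before z-scoring (default 1: none).
#' @return list of class `ps_validation_report`: per-variable
#'   alignments, distances, rescaled distances, phase-agreement
#'   fraction, records used.
#' @export
compare_simulation_proxy <- function(cube, records, similarity,
                                     pattern = "rj6c", window,
                                     region = NULL,
                                     min_similarity = 0.7, min_dates = 5L,
                                     smooth_years = 1L) {
  sel <- select_records(records, similarity, min_similarity, min_dates,
                        window)
  if (length(sel) == 0L)
    stop("no proxy record passes the similarity/dating selection")

  if (is.null(region)) {
    i0 <- cube$geom$nrow %/% 2L; j0 <- cube$geom$ncol %/% 2L
    region <- cbind(row = c(i0, i0, i0 + 1L, i0 + 1L),
                    col = c(j0, j0 + 1L, j0, j0 + 1L))
  }
  sim <- annual_aggregate(cube, region)
  sim <- sim[sim$year >= window[1] & sim$year <= window[2], ]
  if (smooth_years > 1L) {
    sim$temperature <- moving_average(sim$temperature, smooth_years)
    sim$precipitation <- moving_average(sim$precipitation, smooth_years)
  }

  interp <- suppressWarnings(
    lapply(sel, function(r) interpolate_record(r, sim$year)))
  common <- Reduce(intersect, lapply(interp, function(s) s$year))
  if (length(common) < 10L)
    stop("records share fewer than 10 common years inside the window")
  interp <- lapply(interp, function(s) s[match(common, s$year), ])
  proxy <- composite_series(interp)
  simc <- sim[match(common, sim$year), ]

  out <- list(records_used = vapply(sel, function(r) r$site_id, ""),
              n_years = length(common), window = window)
  for (v in c("temperature", "precipitation")) {
    qz <- zscore(simc[[v]])
    rz <- zscore(proxy[[v]])
    al <- dtw_align(qz, rz, pattern)
    out[[v]] <- list(
      alignment = al,
      distance = al$distance,
      normalized_distance = al$normalized_distance,
      ## z-distance re-expressed in physical units via the simulation SD
      rescaled_distance = al$normalized_distance * stats::sd(simc[[v]]),
      median_path_offset = path_offset(al))
  }
  agree <- classify_phase(zscore(simc$temperature),
                          zscore(simc$precipitation)) ==
    classify_phase(zscore(proxy$temperature), zscore(proxy$precipitation))
  out$phase_agreement <- mean(agree)
  class(out) <- "ps_validation_report"
  out
}

#' @export
print.ps_validation_report <- function(x, ...) {
  cat(sprintf("<ps_validation_report: %d records, %d years>\n",
              length(x$records_used), x$n_years))
  for (v in c("temperature", "precipitation"))
    cat(sprintf("  %-13s dtw distance %.3f (normalized %.3f), offset %g\n",
                v, x[[v]]$distance, x[[v]]$normalized_distance,
                x[[v]]$median_path_offset))
  cat(sprintf("  phase agreement %.1f%%\n", 100 * x$phase_agreement))
  invisible(x)
}
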