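#' Aggregate a climate cube to an annual regional series
#'
#' Per year, temperature is the mean over the 12 months and the region's
#' cells; precipitation is the sum over months of the region-mean monthly
#' precipitation (an annual total in mm).
#'
#' @param cube `ps_cube`.
#' @param region integer matrix with columns `row`, `col` (coarse grid).
#' @return data.frame with `year`, `temperature`, `precipitation`.
#' @export
annual_aggregate <- function(cube, region) {
  region <- as.matrix(region)
  if (nrow(region) == 0L) stop("region must contain at least one cell")
  if (any(region[, 1] < 1 | region[, 1] > cube$geom$nrow |
            region[, 2] < 1 | region[, 2] > cube$geom$ncol))
    stop("region cell outside the cube grid")
  ny <- length(cube$years)
  tv <- numeric(ny); pv <- numeric(ny)
  for (k in seq_len(nrow(region))) {
    i <- region[k, 1]; j <- region[k, 2]
    tv <- tv + rowMeans(cube$temperature[, , i, j, drop = TRUE])
    pv <- pv + rowSums(cube$precipitation[, , i, j, drop = TRUE])
  }
  data.frame(year = cube$years,
             temperature = tv / nrow(region),
             precipitation = pv / nrow(region))
}

#' Centred moving average with symmetric edge shrinkage
#'
#' Interior points use a symmetric window of half-width `floor(window/2)`;
#' for even windows the two extreme lags receive half weight (the
#' climatological centred even-window mean), so a linear series is left
#' exactly unchanged in the interior. Near the edges the half-width
#' shrinks symmetrically to what the series supports.
#'
#' @param x numeric series.
#' @param window window length in samples (default 20).
#' @return smoothed series aligned to the input.
#' @export
moving_average <- function(x, window = 20L) {
  n <- length(x)
  if (window < 1) stop("window must be >= 1")
  if (window > n) stop("window longer than the series")
  if (window == 1L) return(x)
  h <- window %/% 2L
  half_weight_ends <- window %% 2L == 0L
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- min(h, i - 1L, n - i)
    k <- (i - hi):(i + hi)
    w <- rep(1, length(k))
    if (half_weight_ends && hi == h && length(k) > 1L) {
      w[1] <- 0.5; w[length(k)] <- 0.5
    }
    out[i] <- sum(w * x[k]) / sum(w)
  }
  out
}

#' Standardize a series against a baseline window
#'
#' `(x - mean) / sd` with the sample mean and SD taken over the baseline
#' positions only; values outside the baseline are standardized with the
#' baseline moments.
#'
#' @param x numeric series.
#' @param baseline integer indices of the baseline window (default: the
#'   whole series).
#' @return z-scored series.
#' @export
zscore <- function(x, baseline = seq_along(x)) {
  if (length(baseline) < 2L) stop("baseline needs at least 2 values")
  mu <- mean(x[baseline]); sd <- stats::sd(x[baseline])
  if (!is.finite(sd) || sd == 0)
    stop("zero standard deviation over the baseline window (constant series)")
  (x - mu) / sd
}

#' Classify years into climate phases from z-score signs
#'
#' Quadrant labels from the signs of the temperature and precipitation
#' z-scores; `z >= 0` counts as "warmer"/"wetter" (boundary convention).
#'
#' @param temp_z,precip_z z-scored series on the same years.
#' @return factor with levels `warmer-wetter`, `warmer-drier`,
#'   `colder-wetter`, `colder-drier`.
#' @export
classify_phase <- function(temp_z, precip_z) {
  if (length(temp_z) != length(precip_z))
    stop("temperature and precipitation series differ in length")
  lab <- ifelse(temp_z >= 0,
                ifelse(precip_z >= 0, "warmer-wetter", "warmer-drier"),
                ifelse(precip_z >= 0, "colder-wetter", "colder-drier"))
  factor(lab, levels = c("warmer-wetter", "warmer-drier",
                         "colder-wetter", "colder-drier"))
}

#' Snapshot climatology of a climate cube
#'
#' Means each month over the half-open window `[start, start + length)`,
#' yielding the 12-month coarse climatology of one quasi-stationary
#' climate state.
#'
#' @param cube `ps_cube`.
#' @param start first year of the window.
#' @param window_length window length in years (default 20).
#' @param label optional label (default from [window_label()]).
#' @return coarse `ps_climatology`.
#' @export
snapshot_mean <- function(cube, start, window_length = 20L, label = NULL) {
  yrs <- start:(start + window_length - 1L)
  if (!all(yrs %in% cube$years))
    stop("window [", start, ", ", start + window_length,
         ") not fully inside the cube's years")
  idx <- match(yrs, cube$years)
  nr <- cube$geom$nrow; nc <- cube$geom$ncol
  tm <- array(0, c(nr, nc, 12L)); pm <- tm
  for (m in 1:12) {
    tm[, , m] <- apply(cube$temperature[idx, m, , , drop = FALSE], c(3, 4), mean)
    pm[, , m] <- apply(cube$precipitation[idx, m, , , drop = FALSE], c(3, 4), mean)
  }
  climatology(tm, pm, cube$geom,
              label = label %||% window_label(start, window_length),
              window = c(start, start + window_length - 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
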