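#' Trapezoidal fuzzy membership
#'
#' 0 at or outside the absolute range, 1 inside the optimal range, linear
#' on the ramps. Degenerate edges (`amin == omin` or `omax == amax`)
#' score 1 at the shared boundary: the plateau wins.
#'
#' @param x numeric vector/matrix of parameter values.
#' @param t `ps_trapezoid`.
#' @return memberships in [0, 1], same shape as `x`; NA propagates.
#' @export
trapezoid_membership <- function(x, t) {
  out <- x * 0
  ## rising ramp
  if (t$omin > t$amin) {
    idx <- which(x > t$amin & x < t$omin)
    out[idx] <- (x[idx] - t$amin) / (t$omin - t$amin)
  }
  ## falling ramp
  if (t$amax > t$omax) {
    idx <- which(x > t$omax & x < t$amax)
    out[idx] <- (t$amax - x[idx]) / (t$amax - t$omax)
  }
  out[which(x >= t$omin & x <= t$omax)] <- 1
  out
}

## texture translation constants: clay-% breaks between light/moderate/heavy
## and the half-width of the linear transition bands
texture_breaks_default <- c(light_heavy = 18, moderate_heavy = 35)
texture_band_default <- 5

#' Fuzzy soil-texture membership
#'
#' Translates a cell's grain-size composition into degrees of the three
#' texture classes (light / moderate / heavy) via clay-fraction
#' trapezoids: fully light below `breaks[1] - band`, fully heavy above
#' `breaks[2] + band`, with linear transitions of half-width `band`
#' centred on the two breaks (the three degrees always sum to 1). The
#' membership is the degree-weighted mean of the crop's class
#' suitabilities.
#'
#' @param sand,silt,clay percentages summing to 100 per cell.
#' @param crop_table named numeric `c(light=, moderate=, heavy=)` in [0,1].
#' @param breaks clay-% class boundaries (default 18 and 35).
#' @param band transition half-width in clay % (default 5).
#' @return memberships in [0, 1], same shape as `clay`.
#' @export
texture_membership <- function(sand, silt, clay, crop_table,
                               breaks = texture_breaks_default,
                               band = texture_band_default) {
  s <- sand + silt + clay
  if (any(abs(s - 100) > 1e-6, na.rm = TRUE))
    stop("sand + silt + clay must sum to 100 per cell")
  breaks <- unname(breaks)
  ramp_down <- function(x, at)
    pmin(pmax((at + band - x) / (2 * band), 0), 1)
  light <- ramp_down(clay, breaks[1])
  notheavy <- ramp_down(clay, breaks[2])
  heavy <- 1 - notheavy
  moderate <- notheavy - light
  (light * crop_table[["light"]] + moderate * crop_table[["moderate"]] +
     heavy * crop_table[["heavy"]])   # degrees already sum to 1
}

## per-cell static memberships (everything that does not depend on the
## growing window), as an n-cell vector
static_membership <- function(statics, crop) {
  n <- statics$geom$nrow * statics$geom$ncol
  m <- pmin(
    trapezoid_membership(as.vector(statics$slope), crop$slope),
    trapezoid_membership(as.vector(statics$twi), crop$twi),
    trapezoid_membership(as.vector(statics$wind), crop$wind),
    trapezoid_membership(as.vector(statics$ph), crop$ph))
  pmin(m, as.vector(texture_membership(statics$sand, statics$silt,
                                       statics$clay, crop$texture)))
}

#' Suitability of one growing window
#'
#' Scores the window starting at `start_month` (months wrap circularly)
#' for a single cell: the minimum over the window's monthly-temperature
#' memberships, the membership of the cumulative precipitation, the
#' minimum monthly solar membership, and all static memberships — the law
#' of the minimum. If the crop has a kill temperature and any window
#' month falls below it, the window scores 0.
#'
#' @param temp_monthly,prec_monthly,solar_monthly numeric length-12
#'   monthly values at the cell.
#' @param statics_cell named list/vector with `slope`, `twi`, `wind`,
#'   `ph`, `sand`, `silt`, `clay` at the cell.
#' @param crop `ps_crop`.
#' @param start_month integer in 1..12.
#' @return scalar suitability in [0, 1].
#' @export
window_score <- function(temp_monthly, prec_monthly, solar_monthly,
                         statics_cell, crop, start_month) {
  stopifnot(start_month >= 1, start_month <= 12)
  mo <- ((start_month - 1L + seq_len(crop$duration_months) - 1L) %% 12L) + 1L
  if (!is.na(crop$kill_temperature) &&
        any(temp_monthly[mo] < crop$kill_temperature)) return(0)
  terms <- c(
    min(trapezoid_membership(temp_monthly[mo], crop$temperature)),
    trapezoid_membership(sum(prec_monthly[mo]), crop$precipitation),
    min(trapezoid_membership(solar_monthly[mo], crop$solar)),
    trapezoid_membership(statics_cell$slope, crop$slope),
    trapezoid_membership(statics_cell$twi, crop$twi),
    trapezoid_membership(statics_cell$wind, crop$wind),
    trapezoid_membership(statics_cell$ph, crop$ph),
    texture_membership(statics_cell$sand, statics_cell$silt,
                       statics_cell$clay, crop$texture))
  min(terms)
}

#' Crop suitability map
#'
#' Evaluates the niche model on every fine-grid cell: the best (maximum)
#' window score over the 12 candidate start months, each window scored by
#' the law of the minimum over dynamic (monthly temperature, cumulative
#' precipitation, monthly solar radiation) and static (slope, TWI, wind,
#' pH, texture) parameters. Vectorized over cells.
#'
#' @param snapshot fine `ps_climatology` (downscaled climate state).
#' @param statics `ps_statics` on the same grid.
#' @param crop `ps_crop`.
#' @return object of class `ps_suitability`: `values` matrix in [0, 1],
#'   `classes` (five-class integer matrix, see [normalize_classify()]),
#'   `crop`, `snapshot` label, `geom`.
#' @export
crop_suitability <- function(snapshot, statics, crop) {
  stop_if_misaligned(snapshot$geom, statics$geom, "snapshot", "statics")
  g <- snapshot$geom
  n <- g$nrow * g$ncol
  tm <- matrix(snapshot$temperature, n, 12L)
  pm <- matrix(snapshot$precipitation, n, 12L)
  sm <- matrix(statics$solar, n, 12L)

  s_static <- static_membership(statics, crop)
  tmemb <- trapezoid_membership(tm, crop$temperature)
  smemb <- trapezoid_membership(sm, crop$solar)

  best <- rep(0, n)
  for (start in 1:12) {
    mo <- ((start - 1L + seq_len(crop$duration_months) - 1L) %% 12L) + 1L
    tt <- do.call(pmin, lapply(mo, function(m) tmemb[, m]))
    ss <- do.call(pmin, lapply(mo, function(m) smemb[, m]))
    pp <- trapezoid_membership(rowSums(pm[, mo, drop = FALSE]),
                               crop$precipitation)
    sc <- pmin(tt, pp, ss, s_static)
    if (!is.na(crop$kill_temperature)) {
      killed <- do.call(pmin, lapply(mo, function(m) tm[, m])) <
        crop$kill_temperature
      sc[which(killed)] <- 0
    }
    best <- pmax(best, sc)
  }
  vals <- matrix(best, g$nrow, g$ncol)
  structure(list(values = vals, classes = normalize_classify(vals),
                 crop = crop$name, snapshot = snapshot$label, geom = g),
            class = "ps_suitability")
}

#' Five-class suitability levels
#' @return character vector of the class names, lowest first.
#' @export
suitability_classes <- function() {
  c("very low", "low", "moderate", "high", "very high")
}

#' Normalize suitability values and classify into five classes
#'
#' Values in [0, 1] are expressed in percent and binned with fixed
#' equal-width edges at 20/40/60/80 %, intervals closed on the left
#' (`[0,20)` very low ... `[80,100]` very high). The edges are global
#' across crops and snapshots so class-share series are comparable.
#'
#' @param values numeric matrix/vector in [0, 1]; NA propagates.
#' @return integer matrix/vector of class codes 1..5 with the class names
#'   in attribute `levels`.
#' @export
normalize_classify <- function(values) {
  pct <- values * 100
  cls <- findInterval(pct, c(20, 40, 60, 80)) + 1L
  cls[!is.finite(pct)] <- NA_integer_
  if (is.matrix(values)) cls <- matrix(cls, nrow(values), ncol(values))
  attr(cls, "levels") <- suitability_classes()
  cls
}
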