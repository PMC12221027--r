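#' Trapezoidal tolerance range
#'
#' The fuzzy reading of a crop's absolute and optimal ranges for one
#' environmental parameter: membership is 0 outside `[amin, amax]`, 1
#' inside `[omin, omax]`, linear on the two ramps.
#'
#' @param amin,omin,omax,amax range corners, `amin <= omin <= omax <= amax`.
#' @return object of class `ps_trapezoid`.
#' @export
trapezoid <- function(amin, omin, omax, amax) {
  if (!(amin <= omin && omin <= omax && omax <= amax))
    stop("trapezoid requires amin <= omin <= omax <= amax")
  structure(list(amin = amin, omin = omin, omax = omax, amax = amax),
            class = "ps_trapezoid")
}

#' @export
print.ps_trapezoid <- function(x, ...) {
  cat(sprintf("<trapezoid %g | %g .. %g | %g>\n", x$amin, x$omin, x$omax, x$amax))
  invisible(x)
}

## parameters every crop must carry a trapezoid for
crop_dynamic_params <- c("temperature", "precipitation")
crop_static_params <- c("slope", "twi", "wind", "solar", "ph")

#' Crop tolerance parameter set
#'
#' @param name crop name.
#' @param duration_months growing-period length, whole months in 1..12.
#' @param temperature trapezoid on monthly mean temperature (degC).
#' @param precipitation trapezoid on the precipitation sum over the
#'   growing window (mm).
#' @param slope,twi,wind,solar,ph trapezoids on the static parameters
#'   (degrees, index, index, W/m2, pH units).
#' @param texture named numeric `c(light=, moderate=, heavy=)` suitability
#'   of the three texture classes, each in [0,1].
#' @param kill_temperature optional monthly-mean temperature (degC) below
#'   which any window month annuls the window (`NA` disables it).
#' @return object of class `ps_crop`.
#' @export
crop_params <- function(name, duration_months, temperature, precipitation,
                        slope, twi, wind, solar, ph,
                        texture = c(light = 1, moderate = 1, heavy = 1),
                        kill_temperature = NA_real_) {
  stopifnot(duration_months >= 1, duration_months <= 12)
  traps <- list(temperature = temperature, precipitation = precipitation,
                slope = slope, twi = twi, wind = wind, solar = solar, ph = ph)
  for (nm in names(traps))
    if (!inherits(traps[[nm]], "ps_trapezoid"))
      stop("parameter '", nm, "' must be a ps_trapezoid")
  texture <- texture[c("light", "moderate", "heavy")]
  if (anyNA(texture) || any(texture < 0 | texture > 1))
    stop("texture table must give light/moderate/heavy values in [0,1]")
  structure(c(list(name = name,
                   duration_months = as.integer(duration_months)),
              traps,
              list(texture = texture, kill_temperature = kill_temperature)),
            class = "ps_crop")
}

#' @export
print.ps_crop <- function(x, ...) {
  cat(sprintf("<ps_crop '%s', %d-month season>\n", x$name, x$duration_months))
  invisible(x)
}

random_trapezoid <- function(centre, half_opt, ramp) {
  trapezoid(centre - half_opt - ramp, centre - half_opt,
            centre + half_opt, centre + half_opt + ramp)
}

#' Generate random crop parameter sets
#'
#' Draws plausible annual-crop tolerance sets with the absolute range
#' strictly containing the optimal range for every parameter (constructive
#' guarantee), for testing the niche engine without real crop tables.
#'
#' @param n number of crops (>= 1).
#' @param seed integer seed.
#' @return list of `ps_crop` of length `n`.
#' @export
generate_crops <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  with_seed(stage_seed(seed, "crops"), {
    lapply(seq_len(n), function(i) {
      dur <- sample(3:9, 1L)
      crop_params(
        name = sprintf("crop%02d", i),
        duration_months = dur,
        temperature = random_trapezoid(stats::runif(1, 10, 20),
                                       stats::runif(1, 3, 6),
                                       stats::runif(1, 2, 6)),
        precipitation = random_trapezoid(stats::runif(1, 45, 90) * dur,
                                         stats::runif(1, 15, 30) * dur,
                                         stats::runif(1, 10, 25) * dur),
        slope = trapezoid(0, 0, stats::runif(1, 4, 9), stats::runif(1, 12, 25)),
        twi = random_trapezoid(stats::runif(1, 6, 9), stats::runif(1, 2, 3),
                               stats::runif(1, 2, 4)),
        wind = trapezoid(0, 0, stats::runif(1, 0.7, 1.0),
                         stats::runif(1, 1.2, 1.8)),
        solar = random_trapezoid(stats::runif(1, 150, 200),
                                 stats::runif(1, 60, 90),
                                 stats::runif(1, 40, 80)),
        ph = random_trapezoid(stats::runif(1, 6, 7.5), stats::runif(1, 0.7, 1.2),
                              stats::runif(1, 0.5, 1.5)),
        texture = c(light = stats::runif(1, 0.4, 1),
                    moderate = 1,
                    heavy = stats::runif(1, 0, 0.8)))
    })
  })
}

#' Build a sentinel crop from a known sub-region of a synthetic world
#'
#' Recovery-test instrument: the optimal box of every parameter is the
#' observed range of that parameter over `cells` (widened by a small
#' margin), and the absolute box is strictly wider, so suitability must be
#' exactly 1 on those cells; texture suitability is 1 for every class.
#'
#' @param snapshot `ps_climatology` supplying monthly climate.
#' @param statics `ps_statics`.
#' @param cells integer matrix with columns `row`, `col` on the fine grid.
#' @param duration_months growing-period length.
#' @param margin relative widening of the optimal box (fraction of the
#'   observed span, with an absolute floor).
#' @return `ps_crop` named `"sentinel"`.
#' @export
sentinel_crop <- function(snapshot, statics, cells, duration_months = 4L,
                          margin = 0.05) {
  stop_if_misaligned(snapshot$geom, statics$geom, "snapshot", "statics")
  idx <- cells[, c("row", "col"), drop = FALSE]
  rng <- function(vals) {
    r <- range(vals)
    pad <- max(margin * (r[2] - r[1]), 1e-6)
    c(r[1] - pad, r[2] + pad)
  }
  box <- function(vals, ramp_frac = 0.5) {
    o <- rng(vals)
    ramp <- max(ramp_frac * (o[2] - o[1]), 1e-3)
    trapezoid(o[1] - ramp, o[1], o[2], o[2] + ramp)
  }
  month_vals <- function(arr) as.vector(apply(arr, 3L, function(m) m[idx]))
  win_prec <- function() {
    ## precipitation sums over every start month's window
    p <- sapply(1:12, function(s) {
      mo <- ((s - 1L + seq_len(duration_months) - 1L) %% 12L) + 1L
      v <- 0
      for (m in mo) v <- v + snapshot$precipitation[, , m][idx]
      v
    })
    as.vector(p)
  }
  crop_params(
    name = "sentinel", duration_months = duration_months,
    temperature = box(month_vals(snapshot$temperature)),
    precipitation = box(win_prec()),
    slope = box(statics$slope[idx]),
    twi = box(statics$twi[idx]),
    wind = box(statics$wind[idx]),
    solar = box(month_vals(statics$solar)),
    ph = box(statics$ph[idx]),
    texture = c(light = 1, moderate = 1, heavy = 1))
}
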