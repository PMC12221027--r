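#' Reference evaluators
#'
#' Deliberately naive re-implementations used as independent
#' cross-checks of the optimized pipeline code: an exhaustive
#' monotone-path enumeration for DTW and a scalar loop evaluator for the
#' niche engine. They share no code with the fast paths.
#'
#' @name reference-evaluators
NULL

## scalar trapezoid membership as an explicit if/else chain
memb_scalar <- function(x, amin, omin, omax, amax) {
  if (is.na(x)) return(NA_real_)
  if (x >= omin && x <= omax) return(1)
  if (x <= amin || x >= amax) return(0)
  if (x < omin) return((x - amin) / (omin - amin))
  (amax - x) / (amax - omax)
}

#' Brute-force crop suitability
#'
#' Loops over every cell, all 12 start months and every parameter with
#' scalar arithmetic; the law of the minimum within a window, the
#' maximum over start months. Independent oracle for
#' [crop_suitability()].
#'
#' @param snapshot fine `ps_climatology`.
#' @param statics `ps_statics`.
#' @param crop `ps_crop`.
#' @return matrix of suitability values.
#' @export
suitability_brute_force <- function(snapshot, statics, crop) {
  g <- snapshot$geom
  out <- matrix(NA_real_, g$nrow, g$ncol)
  tb <- function(tz) c(tz$amin, tz$omin, tz$omax, tz$amax)
  bt <- tb(crop$temperature); bp <- tb(crop$precipitation)
  bs <- tb(crop$slope); bw <- tb(crop$twi); bwd <- tb(crop$wind)
  bso <- tb(crop$solar); bph <- tb(crop$ph)
  for (r in seq_len(g$nrow)) for (cc in seq_len(g$ncol)) {
    ## texture degrees via the same published breaks, scalar arithmetic
    clay <- statics$clay[r, cc]
    light <- min(1, max(0, (texture_breaks_default[[1]] +
                              texture_band_default - clay) /
                            (2 * texture_band_default)))
    notheavy <- min(1, max(0, (texture_breaks_default[[2]] +
                                 texture_band_default - clay) /
                               (2 * texture_band_default)))
    tex <- light * crop$texture[["light"]] +
      (notheavy - light) * crop$texture[["moderate"]] +
      (1 - notheavy) * crop$texture[["heavy"]]
    stat <- min(
      memb_scalar(statics$slope[r, cc], bs[1], bs[2], bs[3], bs[4]),
      memb_scalar(statics$twi[r, cc], bw[1], bw[2], bw[3], bw[4]),
      memb_scalar(statics$wind[r, cc], bwd[1], bwd[2], bwd[3], bwd[4]),
      memb_scalar(statics$ph[r, cc], bph[1], bph[2], bph[3], bph[4]),
      tex)
    best <- 0
    for (start in 1:12) {
      months <- ((start - 1 + 0:(crop$duration_months - 1)) %% 12) + 1
      score <- stat
      psum <- 0
      killed <- FALSE
      for (m in months) {
        tv <- snapshot$temperature[r, cc, m]
        if (!is.na(crop$kill_temperature) && tv < crop$kill_temperature)
          killed <- TRUE
        score <- min(score, memb_scalar(tv, bt[1], bt[2], bt[3], bt[4]))
        score <- min(score, memb_scalar(statics$solar[r, cc, m],
                                        bso[1], bso[2], bso[3], bso[4]))
        psum <- psum + snapshot$precipitation[r, cc, m]
      }
      score <- min(score, memb_scalar(psum, bp[1], bp[2], bp[3], bp[4]))
      if (killed) score <- 0
      best <- max(best, score)
    }
    out[r, cc] <- best
  }
  out
}

#' Exhaustive DTW distance by monotone-path enumeration
#'
#' Enumerates every monotone path built from the elementary moves
#' (1,1), (1,0), (0,1) between the anchored endpoints and returns the
#' minimum accumulated cost, with the diagonal move weighted
#' `diag_weight` (1 for symmetric1, 2 for symmetric2) and side moves
#' weighted 1; the local cost at (1,1) is always included. Tractable for
#' series up to length ~7.
#'
#' @param query,reference numeric series.
#' @param diag_weight weight of the diagonal move.
#' @param local_cost `"absolute"` or `"squared"`.
#' @return minimum accumulated distance.
#' @export
dtw_brute_force <- function(query, reference, diag_weight = 1,
                            local_cost = c("absolute", "squared")) {
  local_cost <- match.arg(local_cost)
  n <- length(query); m <- length(reference)
  d <- outer(query, reference, function(a, b)
    if (local_cost == "absolute") abs(a - b) else (a - b)^2)
  best <- Inf
  recurse <- function(i, j, acc) {
    if (acc >= best) return(invisible())
    if (i == n && j == m) { best <<- acc; return(invisible()) }
    if (i < n && j < m) recurse(i + 1, j + 1, acc + diag_weight * d[i + 1, j + 1])
    if (i < n) recurse(i + 1, j, acc + d[i + 1, j])
    if (j < m) recurse(i, j + 1, acc + d[i, j + 1])
    invisible()
  }
  recurse(1, 1, d[1, 1])
  best
}
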