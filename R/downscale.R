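#' Delta-method downscaling of a coarse snapshot onto a fine reference
#'
#' Per month and variable the coarse anomaly (snapshot minus baseline) is
#' computed pixel-wise, interpolated bilinearly to the fine grid over a
#' one-cell replicated padding (so edges carry no extrapolation
#' artefacts), and added to the fine reference climatology. Precipitation
#' can alternatively be adjusted by the coarse ratio; the additive
#' difference is the default. Negative precipitation is clamped at 0.
#'
#' @param snapshot_coarse,baseline_coarse coarse `ps_climatology` on the
#'   same grid.
#' @param reference_fine fine `ps_climatology` covering the same extent,
#'   dimensions an odd integer multiple of the coarse grid.
#' @param precip_method `"additive"` (default) or `"ratio"`.
#' @return fine `ps_climatology` labelled like the snapshot.
#' @export
delta_downscale <- function(snapshot_coarse, baseline_coarse, reference_fine,
                            precip_method = c("additive", "ratio")) {
  precip_method <- match.arg(precip_method)
  stop_if_misaligned(snapshot_coarse$geom, baseline_coarse$geom,
                     "snapshot", "baseline")
  f <- reference_fine$geom$nrow / snapshot_coarse$geom$nrow
  if (f != round(f) ||
        reference_fine$geom$ncol != snapshot_coarse$geom$ncol * f)
    stop("grid-extent mismatch: reference fine grid (",
         reference_fine$geom$nrow, "x", reference_fine$geom$ncol,
         ") is not an integer refinement of the coarse grid (",
         snapshot_coarse$geom$nrow, "x", snapshot_coarse$geom$ncol, ")")
  f <- as.integer(f)
  nrF <- reference_fine$geom$nrow; ncF <- reference_fine$geom$ncol
  tout <- array(0, c(nrF, ncF, 12L)); pout <- tout
  for (m in 1:12) {
    anom_t <- snapshot_coarse$temperature[, , m] -
      baseline_coarse$temperature[, , m]
    tout[, , m] <- reference_fine$temperature[, , m] +
      bilinear_refine(anom_t, f)
    if (precip_method == "additive") {
      anom_p <- snapshot_coarse$precipitation[, , m] -
        baseline_coarse$precipitation[, , m]
      pout[, , m] <- pmax(0, reference_fine$precipitation[, , m] +
                            bilinear_refine(anom_p, f))
    } else {
      base <- baseline_coarse$precipitation[, , m]
      ratio <- ifelse(base > 0, snapshot_coarse$precipitation[, , m] / base, 1)
      pout[, , m] <- pmax(0, reference_fine$precipitation[, , m] *
                            bilinear_refine(ratio, f))
    }
  }
  climatology(tout, pout, reference_fine$geom,
              label = snapshot_coarse$label, window = snapshot_coarse$window)
}
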