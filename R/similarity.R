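#' Climate similarity index relative to a reference site
#'
#' For every cell a dissimilarity against the site's 12-month climatology
#' is accumulated over months and variables, each squared difference
#' scaled by the across-grid standard deviation of that variable-month;
#' the index is `exp(-sqrt(D / 12))`, so the site's own cell scores
#' exactly 1 and all values lie in (0, 1]. With `allow_rotation` the
#' minimum over the 12 circular month shifts of the cell's climatology is
#' used, making the index insensitive to a pure seasonal phase shift.
#'
#' @param reference_fine fine `ps_climatology`.
#' @param site integer `c(row, col)` of the reference cell.
#' @param weights numeric `c(temperature =, precipitation =)` term weights.
#' @param allow_rotation compare under circular month shifts (default
#'   FALSE).
#' @return object of class `ps_similarity`: `values` matrix in (0, 1],
#'   `site`, `weights`, `rotation`, `geom`.
#' @export
similarity_index <- function(reference_fine, site,
                             weights = c(temperature = 1, precipitation = 1),
                             allow_rotation = FALSE) {
  g <- reference_fine$geom
  if (site[1] < 1 || site[1] > g$nrow || site[2] < 1 || site[2] > g$ncol)
    stop("site outside the grid")
  n <- g$nrow * g$ncol
  tm <- matrix(reference_fine$temperature, n, 12L)
  pm <- matrix(reference_fine$precipitation, n, 12L)
  scell <- (site[2] - 1L) * g$nrow + site[1]

  sd_t <- apply(tm, 2L, stats::sd)
  sd_p <- apply(pm, 2L, stats::sd)
  use_t <- sd_t > 0; use_p <- sd_p > 0
  if (any(!use_t) || any(!use_p))
    warning("variable-months with zero across-grid sd dropped from the index")

  rots <- if (allow_rotation) 0:11 else 0L
  D <- matrix(Inf, n, 1L)
  for (r in rots) {
    mr <- ((seq_len(12L) - 1L + r) %% 12L) + 1L
    d <- numeric(n)
    for (m in which(use_t))
      d <- d + weights[["temperature"]] *
        (tm[scell, m] - tm[, mr[m]])^2 / sd_t[m]^2
    for (m in which(use_p))
      d <- d + weights[["precipitation"]] *
        (pm[scell, m] - pm[, mr[m]])^2 / sd_p[m]^2
    D <- pmin(D, d)
  }
  sim <- matrix(exp(-sqrt(D / 12)), g$nrow, g$ncol)
  structure(list(values = sim, site = as.integer(site), weights = weights,
                 rotation = allow_rotation, geom = g),
            class = "ps_similarity")
}
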