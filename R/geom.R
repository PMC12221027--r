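#' Grid geometry descriptor
#'
#' Light-weight geometry attached to every gridded object: north-up,
#' row 1 = northern edge, cell-centre registration, half-open pixel extents.
#' All pipeline stages refuse to combine grids whose geometry differs;
#' there is no implicit resampling.
#'
#' @param nrow,ncol grid dimensions (rows, columns).
#' @param xll,yll coordinates of the lower-left *corner* of the grid.
#' @param cellsize cell edge length (map units; the synthetic world uses km).
#' @param crs free-text CRS tag carried through file round trips.
#' @return an object of class `ps_geom`.
#' @export
ps_geom <- function(nrow, ncol, xll = 0, yll = 0, cellsize = 1,
                    crs = "synthetic-cartesian") {
  stopifnot(nrow >= 1, ncol >= 1, cellsize > 0)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 xll = xll, yll = yll, cellsize = cellsize, crs = crs),
            class = "ps_geom")
}

#' @export
print.ps_geom <- function(x, ...) {
  cat(sprintf("<ps_geom %d x %d, cellsize %g, origin (%g, %g), crs '%s'>\n",
              x$nrow, x$ncol, x$cellsize, x$xll, x$yll, x$crs))
  invisible(x)
}

#' Test whether two geometries are identical
#' @param a,b `ps_geom` objects.
#' @param tol numeric tolerance on origin/cellsize.
#' @return logical scalar.
#' @export
same_geom <- function(a, b, tol = 1e-9) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

stop_if_misaligned <- function(a, b, what_a = "first grid",
                               what_b = "second grid") {
  if (!same_geom(a, b)) {
    stop(sprintf(
      "grid misalignment: %s is %dx%d (cell %g) but %s is %dx%d (cell %g)",
      what_a, a$nrow, a$ncol, a$cellsize,
      what_b, b$nrow, b$ncol, b$cellsize), call. = FALSE)
  }
  invisible(TRUE)
}

#' Refine a coarse geometry by an integer factor
#' @param geom coarse `ps_geom`.
#' @param factor integer refinement per axis.
#' @return fine `ps_geom` covering the same extent.
#' @export
refine_geom <- function(geom, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  ps_geom(geom$nrow * factor, geom$ncol * factor,
          xll = geom$xll, yll = geom$yll,
          cellsize = geom$cellsize / factor, crs = geom$crs)
}

## ---- random fields -------------------------------------------------------

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian-smooth a matrix (separable kernel, replicate padding)
#'
#' Used by the synthetic generators to turn white noise into spatially
#' autocorrelated fields. `sigma <= 0` returns the input unchanged.
#'
#' @param m numeric matrix.
#' @param sigma kernel standard deviation in cells.
#' @return matrix of the same dimension.
#' @export
smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  conv1 <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1L):(r + length(v))]
  }
  m2 <- apply(m, 2L, conv1)
  t(apply(m2, 1L, conv1))
}

## standardized smoothed noise field, unit variance
noise_field <- function(nr, nc, sigma) {
  f <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
  s <- stats::sd(f)
  if (s == 0) f else (f - mean(f)) / s
}

## ---- block aggregation and bilinear refinement ---------------------------

#' Block-average a fine matrix onto a coarse grid
#' @param m fine matrix whose dimensions are multiples of `factor`.
#' @param factor integer block edge.
#' @return coarse matrix of block means.
#' @export
block_mean <- function(m, factor) {
  nr <- nrow(m) / factor; nc <- ncol(m) / factor
  stopifnot(nr == round(nr), nc == round(nc))
  ri <- rep(seq_len(nr), each = factor)
  ci <- rep(seq_len(nc), each = factor)
  out <- rowsum(m, ri) / factor          # collapse rows
  t(rowsum(t(out), ci)) / factor          # collapse cols
}

## Evaluate a bilinear surface through coarse-node values at continuous
## fine-grid coordinates. Nodes sit at coarse cell centres; one replicated
## edge node is padded on every side so the interpolant covers the full
## fine extent without extrapolation artefacts.
bilinear_nodes <- function(coarse) {
  nr <- nrow(coarse); nc <- ncol(coarse)
  p <- matrix(NA_real_, nr + 2L, nc + 2L)
  p[2:(nr + 1), 2:(nc + 1)] <- coarse
  p[1, ] <- p[2, ]; p[nr + 2, ] <- p[nr + 1, ]
  p[, 1] <- p[, 2]; p[, nc + 2] <- p[, nc + 1]
  p
}

## positions (in fine-cell units, centre of fine cell r is r) of the padded
## coarse node rows/cols for refinement factor f
node_positions <- function(n_coarse, f) {
  centres <- (seq_len(n_coarse) - 0.5) * f + 0.5
  c(centres[1] - f, centres, centres[n_coarse] + f)
}

#' Bilinearly refine a coarse matrix onto the matching fine grid
#'
#' Coarse values are treated as point values at coarse cell centres, the
#' domain is padded by one replicated node on each side, and the bilinear
#' interpolant is evaluated at every fine cell centre.
#'
#' @param coarse coarse numeric matrix.
#' @param factor integer refinement per axis.
#' @return fine matrix of dimension `dim(coarse) * factor`.
#' @export
bilinear_refine <- function(coarse, factor) {
  p <- bilinear_nodes(coarse)
  py <- node_positions(nrow(coarse), factor)
  px <- node_positions(ncol(coarse), factor)
  fy <- seq_len(nrow(coarse) * factor)
  fx <- seq_len(ncol(coarse) * factor)
  iy <- findInterval(fy, py, rightmost.closed = TRUE)
  ix <- findInterval(fx, px, rightmost.closed = TRUE)
  iy <- pmin(pmax(iy, 1L), length(py) - 1L)
  ix <- pmin(pmax(ix, 1L), length(px) - 1L)
  ty <- (fy - py[iy]) / (py[iy + 1L] - py[iy])
  tx <- (fx - px[ix]) / (px[ix + 1L] - px[ix])
  ## outer products of the four corner contributions
  a <- p[cbind(rep(iy, length(fx)), rep(ix, each = length(fy)))]
  b <- p[cbind(rep(iy, length(fx)), rep(ix + 1L, each = length(fy)))]
  cc <- p[cbind(rep(iy + 1L, length(fx)), rep(ix, each = length(fy)))]
  d <- p[cbind(rep(iy + 1L, length(fx)), rep(ix + 1L, each = length(fy)))]
  wy <- rep(ty, length(fx)); wx <- rep(tx, each = length(fy))
  v <- a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx +
    cc * wy * (1 - wx) + d * wy * wx
  matrix(v, length(fy), length(fx))
}

#' Fine-grid cell holding a coarse cell's centre
#'
#' Only exact when the refinement factor is odd (the coarse centre then
#' coincides with a fine cell centre), which the pipeline's default
#' refinement uses.
#'
#' @param i,j coarse row/column indices.
#' @param factor odd integer refinement.
#' @return list with `row` and `col` fine indices.
#' @export
coarse_centre_cell <- function(i, j, factor) {
  stopifnot(factor %% 2 == 1)
  list(row = (i - 1L) * factor + (factor + 1L) %/% 2L,
       col = (j - 1L) * factor + (factor + 1L) %/% 2L)
}

## run code under a temporary RNG state derived from seed
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

## per-stage seed derivation from one global seed
stage_seed <- function(seed, stage) {
  offsets <- c(terrain = 101L, soil = 211L, climate = 307L, proxy = 401L,
               crops = 503L, pipeline = 601L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) * 7919L + offsets[[stage]]) %% 2147483647L
}
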