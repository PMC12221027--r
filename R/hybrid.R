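#' Trim nearly-unsuitable values
#'
#' Suitability values at or below the threshold are set to 0 (only values
#' strictly above 20 % count, preventing overrepresentation of marginal
#' cells in the hybrid model).
#'
#' @param values numeric matrix/vector in [0, 1].
#' @param threshold trim threshold (default 0.20).
#' @return trimmed values, same shape.
#' @export
trim_suitability <- function(values, threshold = 0.20) {
  values[which(values <= threshold)] <- 0
  values
}

#' Combine per-crop suitability maps into the hybrid rotation model
#'
#' Each crop map is trimmed at the threshold, then combined per cell by
#' the chosen aggregator: `"mean"` (default; trimmed values count as 0),
#' `"min"` (strictest crop after trimming), or `"count-fraction"` (share
#' of crops strictly above the threshold).
#'
#' @param maps list of >= 2 aligned `ps_suitability` objects.
#' @param aggregator `"mean"`, `"min"` or `"count-fraction"`.
#' @param threshold trim threshold (default 0.20).
#' @return object of class `ps_hybrid`: `values`, `classes`, `n_crops`
#'   (contributing-crop count per cell), `aggregator`, `snapshot`, `geom`.
#' @export
hybrid_combine <- function(maps, aggregator = c("mean", "min", "count-fraction"),
                           threshold = 0.20) {
  aggregator <- match.arg(aggregator)
  if (length(maps) < 2L) stop("need at least two crop maps")
  g <- maps[[1]]$geom
  for (m in maps[-1])
    stop_if_misaligned(g, m$geom, maps[[1]]$crop, m$crop)
  arr <- simplify2array(lapply(maps, function(m)
    trim_suitability(m$values, threshold)))
  n_crops <- apply(arr > threshold, c(1, 2), sum)
  vals <- switch(aggregator,
                 "mean" = apply(arr, c(1, 2), mean),
                 "min" = apply(arr, c(1, 2), min),
                 "count-fraction" = n_crops / length(maps))
  structure(list(values = vals, classes = normalize_classify(vals),
                 n_crops = n_crops, aggregator = aggregator,
                 threshold = threshold,
                 snapshot = maps[[1]]$snapshot, geom = g),
            class = "ps_hybrid")
}

#' Binary hybrid map
#'
#' A cell is "suitable" iff the hybrid value is strictly above the
#' threshold (mirroring the trim rule).
#'
#' @param hybrid `ps_hybrid` (or a numeric matrix of hybrid values).
#' @param threshold default 0.20.
#' @return logical matrix.
#' @export
binarize_hybrid <- function(hybrid, threshold = 0.20) {
  v <- if (inherits(hybrid, "ps_hybrid")) hybrid$values else hybrid
  v > threshold
}

#' Areal share of each suitability class
#'
#' @param classes five-class integer layer (from [normalize_classify()]).
#' @param mask optional logical matrix restricting the tally; NA class
#'   cells are excluded.
#' @return named numeric vector of shares over the five classes, summing
#'   to 1.
#' @export
class_area_shares <- function(classes, mask = NULL) {
  keep <- !is.na(classes)
  if (!is.null(mask)) keep <- keep & mask
  if (!any(keep)) stop("empty mask: no cells to tally")
  tab <- tabulate(classes[keep], nbins = 5L)
  stats::setNames(tab / sum(tab), suitability_classes())
}

#' Per-class change in percentage points
#'
#' @param shares_a,shares_b class-share vectors (fractions) over the same
#'   classes.
#' @return named vector of `(b - a) * 100` percentage points; sums to 0.
#' @export
class_change <- function(shares_a, shares_b) {
  if (!identical(names(shares_a), names(shares_b)))
    stop("class sets differ")
  (shares_b - shares_a) * 100
}

## list of aligned matrices -> array with the snapshot index last
## (robust for 1x1 grids, unlike simplify2array)
stack_to_array <- function(stack) {
  d <- dim(stack[[1]])
  array(unlist(stack, use.names = FALSE), dim = c(d, length(stack)))
}

#' Coefficient of variation across a snapshot stack
#'
#' Per cell, sample standard deviation divided by the mean across the
#' stack's layers, in percent. Cells whose temporal mean is 0 (and cells
#' with any NA) are no-data.
#'
#' @param stack list of >= 2 aligned matrices, or a 3-D array with the
#'   snapshot index last.
#' @return matrix of CV in percent, NA where undefined.
#' @export
cv_across_snapshots <- function(stack) {
  arr <- if (is.list(stack)) stack_to_array(stack) else stack
  if (length(dim(arr)) != 3L || dim(arr)[3] < 2L)
    stop("need a stack of at least two layers")
  mu <- apply(arr, c(1, 2), mean)
  sd <- apply(arr, c(1, 2), stats::sd)
  cv <- 100 * sd / mu
  cv[which(mu == 0)] <- NA_real_
  cv
}

#' Number of binary state changes across consecutive snapshots
#'
#' @param stack list of >= 2 aligned logical matrices, or a 3-D logical
#'   array with the snapshot index last.
#' @return integer matrix of transition counts in 0..(n-1).
#' @export
binary_change_sum <- function(stack) {
  arr <- if (is.list(stack)) stack_to_array(stack) else stack
  if (length(dim(arr)) != 3L || dim(arr)[3] < 2L)
    stop("need a stack of at least two layers")
  n <- dim(arr)[3]
  out <- matrix(0L, dim(arr)[1], dim(arr)[2])
  for (k in 2:n) out <- out + (arr[, , k] != arr[, , k - 1])
  out
}
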