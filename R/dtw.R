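#' Dynamic time warping alignment of two series
#'
#' Minimizes the accumulated local cost over monotone warping paths under
#' a step pattern's productions, by dynamic programming with exact
#' backtracking. Both endpoints are anchored: paths start at (1, 1) and
#' end at (n, m). The accumulated distance starts from the local cost at
#' (1, 1); ties between productions are broken toward the first listed
#' (the diagonal, for the shipped patterns). The normalized distance
#' divides by the pattern's divisor (`n`, `m`, `n + m`), and is `NA` for
#' non-normalizable patterns.
#'
#' @param query,reference numeric series (typically z-scores), length >= 2.
#' @param pattern `ps_step_pattern` or a pattern name for
#'   [step_pattern_by_name()] (default `"symmetric2"`).
#' @param local_cost `"absolute"` (|q - r|) or `"squared"` ((q - r)^2).
#' @return object of class `ps_alignment`: `distance`,
#'   `normalized_distance`, `path` (two-column matrix of index pairs),
#'   `pattern`, `n`, `m`.
#' @export
dtw_align <- function(query, reference, pattern = "symmetric2",
                      local_cost = c("absolute", "squared")) {
  local_cost <- match.arg(local_cost)
  if (is.character(pattern)) pattern <- step_pattern_by_name(pattern)
  n <- length(query); m <- length(reference)
  if (n < 2L || m < 2L) stop("both series need length >= 2")
  d <- outer(query, reference, function(a, b)
    if (local_cost == "absolute") abs(a - b) else (a - b)^2)

  np <- length(pattern$productions)
  deltas <- t(vapply(pattern$productions, prod_delta, numeric(2)))
  ## per production: row/col offsets (relative to the current cell) of the
  ## weighted local costs it accumulates
  offs <- lapply(pattern$productions, function(p) {
    pos <- apply(p$moves, 2L, cumsum)
    if (nrow(p$moves) == 1L) pos <- matrix(pos, 1L)
    di <- sum(p$moves[, 1]) - pos[, 1]
    dj <- sum(p$moves[, 2]) - pos[, 2]
    list(di = di, dj = dj, w = p$weights)
  })
  vert <- which(deltas[, 1] >= 1L)   # cross-row productions: vectorize over j
  horiz <- which(deltas[, 1] == 0L)  # within-row: sequential left-to-right
  g <- matrix(Inf, n, m)
  choice <- matrix(0L, n, m)
  g[1, 1] <- d[1, 1]
  js <- seq_len(m)
  for (i in 1:n) {
    row_best <- g[i, ]; row_choice <- choice[i, ]
    for (p in vert) {
      pi <- i - deltas[p, 1]
      if (pi < 1L) next
      jv <- js[js - deltas[p, 2] >= 1L]
      acc <- g[pi, jv - deltas[p, 2]]
      o <- offs[[p]]
      for (k in seq_along(o$w))
        acc <- acc + o$w[k] * d[i - o$di[k], jv - o$dj[k]]
      upd <- which(acc < row_best[jv])
      if (length(upd)) {
        row_best[jv[upd]] <- acc[upd]
        row_choice[jv[upd]] <- p
      }
    }
    if (length(horiz) && m > 1L) {
      for (j in 2:m) {
        for (p in horiz) {
          pj <- j - deltas[p, 2]
          if (pj < 1L) next
          o <- offs[[p]]
          acc <- row_best[pj] + sum(o$w * d[i, j - o$dj])
          if (acc < row_best[j]) { row_best[j] <- acc; row_choice[j] <- p }
        }
      }
    }
    g[i, ] <- row_best; choice[i, ] <- row_choice
  }
  if (!is.finite(g[n, m]))
    stop("no feasible warping path under this step pattern ",
         "(series length ratio exceeds its slope constraint)")

  ## backtrack, expanding each production's intermediate points
  path <- list(c(n, m))
  i <- n; j <- m
  while (!(i == 1L && j == 1L)) {
    p <- pattern$productions[[choice[i, j]]]
    pi <- i - sum(p$moves[, 1]); pj <- j - sum(p$moves[, 2])
    ## intermediate points from predecessor (exclusive) to current (exclusive)
    ci <- pi; cj <- pj
    pts <- list()
    for (k in seq_len(nrow(p$moves))) {
      ci <- ci + p$moves[k, 1]; cj <- cj + p$moves[k, 2]
      pts[[k]] <- c(ci, cj)
    }
    pts[[length(pts)]] <- NULL            # current cell already recorded
    path <- c(list(c(pi, pj)), pts, path)
    i <- pi; j <- pj
  }
  path <- do.call(rbind, path)
  colnames(path) <- c("query", "reference")

  divisor <- switch(pattern$norm, "none" = NA_real_, "n" = n, "m" = m,
                    "n+m" = n + m)
  structure(list(distance = g[n, m],
                 normalized_distance = g[n, m] / divisor,
                 path = path, pattern = pattern$name, n = n, m = m),
            class = "ps_alignment")
}

#' @export
print.ps_alignment <- function(x, ...) {
  cat(sprintf(
    "<ps_alignment %d x %d, pattern %s, distance %.4g, normalized %.4g>\n",
    x$n, x$m, x$pattern, x$distance, x$normalized_distance))
  invisible(x)
}

#' Median vertical offset of an alignment path
#'
#' `median(reference index - query index)` over the path; for a proxy
#' lagging the simulation by k years this recovers approximately k.
#'
#' @param alignment `ps_alignment`.
#' @return numeric scalar.
#' @export
path_offset <- function(alignment) {
  stats::median(alignment$path[, "reference"] - alignment$path[, "query"])
}
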