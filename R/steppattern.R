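#' Construct a DTW step pattern
#'
#' A step pattern is a set of productions, each an ordered sequence of
#' elementary moves `(di, dj)` walked from the predecessor cell to the
#' current cell, with one cost weight per move (the local cost at the
#' point reached by that move is multiplied by the weight). All moves
#' must be monotone (`di, dj >= 0`, `di + dj >= 1`). The normalization
#' rule divides the accumulated distance by the query length (`"n"`),
#' the reference length (`"m"`), their sum (`"n+m"`), or not at all
#' (`"none"`).
#'
#' Productions are tried in list order and ties broken toward the first,
#' so the single-diagonal production should be listed first where
#' diagonal-preferring tie-breaks are wanted.
#'
#' @param name pattern name.
#' @param productions list; each element a list with `moves` (matrix with
#'   columns di, dj) and `weights` (numeric, one per move).
#' @param norm `"none"`, `"n"`, `"m"`, or `"n+m"`.
#' @return object of class `ps_step_pattern`.
#' @export
step_pattern <- function(name, productions, norm = "none") {
  norm <- match.arg(norm, c("none", "n", "m", "n+m"))
  for (p in productions) {
    mv <- p$moves
    if (!is.matrix(mv) || ncol(mv) != 2L)
      stop("each production needs a two-column move matrix")
    if (any(mv < 0) || any(rowSums(mv) < 1))
      stop("moves must satisfy di >= 0, dj >= 0, di + dj >= 1")
    if (length(p$weights) != nrow(mv))
      stop("need one weight per move")
  }
  structure(list(name = name, productions = productions, norm = norm),
            class = "ps_step_pattern")
}

#' @export
print.ps_step_pattern <- function(x, ...) {
  cat(sprintf("<ps_step_pattern '%s', %d productions, norm %s>\n",
              x$name, length(x$productions), x$norm))
  for (p in x$productions) {
    mv <- apply(p$moves, 1L, function(r) sprintf("(%d,%d)", r[1], r[2]))
    cat("  ", paste(sprintf("%s*%g", mv, p$weights), collapse = " + "), "\n")
  }
  invisible(x)
}

prod_delta <- function(p) colSums(p$moves)

#' Built-in symmetric step patterns
#'
#' `symmetric1`: unit-weight diagonal/horizontal/vertical moves, no
#' normalization. `symmetric2`: diagonal weight 2 (so a diagonal costs as
#' much as the two equivalent side steps), normalized by `n + m`.
#'
#' @return `ps_step_pattern`.
#' @export
#' @rdname symmetric_patterns
symmetric1 <- function() {
  step_pattern("symmetric1", list(
    list(moves = matrix(c(1, 1), 1), weights = 1),
    list(moves = matrix(c(1, 0), 1), weights = 1),
    list(moves = matrix(c(0, 1), 1), weights = 1)), norm = "none")
}

#' @export
#' @rdname symmetric_patterns
symmetric2 <- function() {
  step_pattern("symmetric2", list(
    list(moves = matrix(c(1, 1), 1), weights = 2),
    list(moves = matrix(c(1, 0), 1), weights = 1),
    list(moves = matrix(c(0, 1), 1), weights = 1)), norm = "n+m")
}

rj_types_file <- function() {
  system.file("extdata", "rabiner_juang_types.yaml", package = "paleosuit",
              mustWork = TRUE)
}

#' Rabiner-Juang step patterns
#'
#' Builds a pattern of the given local-continuity type (I..VII, read from
#' the production table shipped as package data) with slope weighting
#' `"a"` (min(di, dj) per move), `"b"` (max), `"c"` (di), or `"d"`
#' (di + dj). Weightings `c` and `d` make the distance normalizable by
#' the query length and by `n + m` respectively; `a` and `b` are not
#' normalizable. The `smoothed` variant replaces the per-move weights of
#' each production by their mean.
#'
#' @param type integer 1..7.
#' @param slope_weighting `"a"`, `"b"`, `"c"` or `"d"`.
#' @param smoothed average the weights along each production.
#' @return `ps_step_pattern` named like `"rj6c"`.
#' @export
rabiner_juang_pattern <- function(type, slope_weighting = "d",
                                  smoothed = FALSE) {
  stopifnot(type %in% 1:7)
  slope_weighting <- match.arg(slope_weighting, c("a", "b", "c", "d"))
  tab <- yaml::read_yaml(rj_types_file())[[paste0("type", type)]]
  wfun <- switch(slope_weighting,
                 a = function(di, dj) pmin(di, dj),
                 b = function(di, dj) pmax(di, dj),
                 c = function(di, dj) di,
                 d = function(di, dj) di + dj)
  productions <- lapply(tab, function(moves) {
    mv <- do.call(rbind, moves)
    w <- wfun(mv[, 1], mv[, 2])
    if (smoothed) w <- rep(mean(w), length(w))
    list(moves = mv, weights = w)
  })
  ## diagonal-first ordering for diagonal-preferring tie-breaks
  is_diag <- vapply(productions, function(p)
    nrow(p$moves) == 1L && all(p$moves[1, ] == c(1, 1)), logical(1))
  productions <- c(productions[is_diag], productions[!is_diag])
  norm <- switch(slope_weighting, c = "n", d = "n+m", "none")
  step_pattern(sprintf("rj%d%s%s", type, slope_weighting,
                       if (smoothed) "s" else ""),
               productions, norm = norm)
}

#' Look up a step pattern by name
#'
#' Accepts `"symmetric1"`, `"symmetric2"`, and Rabiner-Juang names in
#' either compact (`"rj6c"`) or roman (`"rj-vi-c"`) form, with an
#' optional trailing `"s"`/`"-smoothed"` for the smoothed variant.
#'
#' @param name pattern name.
#' @return `ps_step_pattern`.
#' @export
step_pattern_by_name <- function(name) {
  if (name == "symmetric1") return(symmetric1())
  if (name == "symmetric2") return(symmetric2())
  x <- tolower(name)
  if (grepl("^rj", x)) {
    smoothed <- grepl("(s|-smoothed)$", x)
    x2 <- sub("(-smoothed|s)$", "", sub("^rj-?", "", x))
    romans <- c(i = 1, ii = 2, iii = 3, iv = 4, v = 5, vi = 6, vii = 7)
    mm <- regmatches(x2, regexec("^([0-9]+|[ivx]+)-?([a-d])$", x2))[[1]]
    if (length(mm) == 3L) {
      type <- suppressWarnings(as.integer(mm[2]))
      if (is.na(type)) type <- romans[[mm[2]]]
      return(rabiner_juang_pattern(type, mm[3], smoothed))
    }
  }
  stop("unknown step pattern: ", name)
}
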