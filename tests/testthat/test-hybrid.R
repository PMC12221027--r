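suit_map <- function(vals, snapshot = "test") {
  m <- matrix(vals, 2, 2)
  structure(list(values = m, classes = normalize_classify(m),
                 crop = "x", snapshot = snapshot, geom = ps_geom(2, 2)),
            class = "ps_suitability")
}

test_that("trimming zeroes marginal values with a strict threshold", {
  expect_equal(trim_suitability(c(0.15, 0.21, 0.20, 0.8)),
               c(0, 0.21, 0, 0.8))
  ## idempotence
  x <- runif(50)
  expect_identical(trim_suitability(trim_suitability(x)),
                   trim_suitability(x))
})

test_that("hybrid combination means trimmed values", {
  a <- suit_map(0.15); b <- suit_map(0.60)
  hy <- hybrid_combine(list(a, b))
  expect_equal(hy$values[1, 1], 0.30)        # (0 + 0.60) / 2
  expect_equal(hy$n_crops[1, 1], 1)

  six <- lapply(1:6, function(i) suit_map(0.5))
  expect_equal(hybrid_combine(six)$values[1, 1], 0.5)

  low <- lapply(1:3, function(i) suit_map(0.20))
  hy0 <- hybrid_combine(low)
  expect_equal(hy0$values[1, 1], 0)
  expect_equal(as.vector(hy0$classes[1, 1]), 1L)   # very low

  ## alternative aggregators
  pair <- list(suit_map(0.3), suit_map(0.9))
  expect_equal(hybrid_combine(pair, "min")$values[1, 1], 0.3)
  expect_equal(hybrid_combine(pair, "count-fraction")$values[1, 1], 1)

  expect_error(hybrid_combine(list(a)), "at least two")
  c_bad <- suit_map(0.5); c_bad$geom <- ps_geom(3, 2)
  expect_error(hybrid_combine(list(a, c_bad)), "misalignment")
})

test_that("hybrid values are bounded by the trimmed crop maximum", {
  w <- small_world()
  crops <- generate_crops(4, seed = 31)
  maps <- lapply(crops, function(cr)
    crop_suitability(w$snapshot, w$statics, cr))
  hy <- hybrid_combine(maps)
  trimmed_max <- Reduce(pmax, lapply(maps, function(m)
    trim_suitability(m$values)))
  expect_true(all(hy$values <= trimmed_max + 1e-12))
  expect_true(all(hy$values >= 0))
  ## zero exactly where all crops fell at or below the threshold
  expect_identical(hy$values == 0, trimmed_max == 0)
})

test_that("binarization mirrors the strict trim rule", {
  expect_true(binarize_hybrid(matrix(0.30))[1, 1])
  expect_false(binarize_hybrid(matrix(0))[1, 1])
  expect_false(binarize_hybrid(matrix(0.20))[1, 1])
})

test_that("class shares count cells and sum to one", {
  cls <- normalize_classify(matrix(c(0.1, 0.15, 0.5, 0.55), 2, 2))
  sh <- class_area_shares(cls)
  expect_equal(as.numeric(sh), c(0.5, 0, 0.5, 0, 0))
  expect_equal(sum(sh), 1)
  ## uniform map: everything in one class
  shu <- class_area_shares(normalize_classify(matrix(0.9, 3, 3)))
  expect_equal(as.numeric(shu), c(0, 0, 0, 0, 1))
  ## 4-cell map with classes VL, VL, M, H
  cls4 <- normalize_classify(matrix(c(0.05, 0.1, 0.5, 0.65), 2, 2))
  expect_equal(as.numeric(class_area_shares(cls4)), c(0.5, 0, 0.25, 0.25, 0))
  expect_error(class_area_shares(cls, mask = matrix(FALSE, 2, 2)),
               "empty mask")
})

test_that("class changes are expressed in percentage points and sum to 0", {
  a <- stats::setNames(c(0.5, 0.5, 0, 0, 0), suitability_classes())
  b <- stats::setNames(c(0.3, 0.7, 0, 0, 0), suitability_classes())
  expect_equal(as.numeric(class_change(a, b)), c(-20, 20, 0, 0, 0))
  expect_equal(as.numeric(class_change(a, a)), rep(0, 5))
  set.seed(4)
  x <- runif(5); x <- x / sum(x); y <- runif(5); y <- y / sum(y)
  names(x) <- names(y) <- suitability_classes()
  expect_lt(abs(sum(class_change(x, y))), 1e-9)
})

test_that("coefficient of variation matches hand arithmetic and scales out", {
  stack <- list(matrix(10, 2, 2), matrix(20, 2, 2), matrix(30, 2, 2))
  cv <- cv_across_snapshots(stack)
  expect_equal(cv[1, 1], 100 * sd(c(10, 20, 30)) / 20)   # 50 %
  ## constant stack: 0 everywhere
  expect_equal(cv_across_snapshots(list(matrix(5, 2, 2), matrix(5, 2, 2))),
               matrix(0, 2, 2))
  ## scale invariance
  scaled <- lapply(stack, function(m) m * 7)
  expect_equal(cv_across_snapshots(scaled), cv)
  ## zero-mean cells are no-data
  z <- cv_across_snapshots(list(matrix(0, 1, 1), matrix(0, 1, 1)))
  expect_true(is.na(z[1, 1]))
  expect_error(cv_across_snapshots(list(matrix(1, 2, 2))), "at least two")
})

test_that("binary change counts transitions between consecutive snapshots", {
  seqs <- c(0, 1, 0, 1, 1)
  stack <- lapply(seqs, function(v) matrix(as.logical(v), 1, 1))
  expect_equal(binary_change_sum(stack)[1, 1], 3L)
  const <- lapply(1:5, function(i) matrix(TRUE, 1, 1))
  expect_equal(binary_change_sum(const)[1, 1], 0L)
  alt <- lapply(c(0, 1, 0, 1, 0), function(v) matrix(as.logical(v), 1, 1))
  expect_equal(binary_change_sum(alt)[1, 1], 4L)   # the n-1 bound, attained
})
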