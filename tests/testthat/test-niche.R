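test_that("trapezoid membership covers plateau, ramps and tails", {
  t <- trapezoid(5, 10, 20, 30)
  expect_equal(trapezoid_membership(15, t), 1)
  expect_equal(trapezoid_membership(7.5, t), 0.5)
  expect_equal(trapezoid_membership(25, t), 0.5)
  expect_equal(trapezoid_membership(40, t), 0)
  expect_equal(trapezoid_membership(5, t), 0)     # closed-out absolute edge
  expect_equal(trapezoid_membership(c(10, 20), t), c(1, 1))
  ## degenerate edge: plateau wins at the shared boundary
  td <- trapezoid(0, 0, 8, 12)
  expect_equal(trapezoid_membership(0, td), 1)
  expect_true(is.na(trapezoid_membership(NA_real_, t)))
  expect_error(trapezoid(5, 4, 6, 7), "amin <= omin")
})

test_that("texture membership follows the clay-fraction translation", {
  tab1 <- c(light = 1, moderate = 0.5, heavy = 0)
  ## fully light cell with a light-loving crop
  expect_equal(texture_membership(70, 20, 10, c(light = 1, moderate = 0,
                                                heavy = 0)), 1)
  ## fully heavy cell, heavy suitability 0
  expect_equal(texture_membership(25, 25, 50, c(light = 0, moderate = 0,
                                                heavy = 0)), 0)
  ## light/moderate transition midpoint (clay = 18): half light, half moderate
  expect_equal(texture_membership(42, 40, 18, c(light = 1, moderate = 0,
                                                heavy = 0)), 0.5)
  ## degrees always sum to one: table of ones gives membership one
  for (clay in c(5, 15, 20, 30, 37, 60))
    expect_equal(texture_membership(50 - clay / 2, 50 - clay / 2, clay,
                                    c(light = 1, moderate = 1, heavy = 1)), 1)
  expect_error(texture_membership(50, 30, 30, tab1), "sum to 100")
})

test_that("window scores apply the law of the minimum", {
  crop <- easy_crop(duration = 3)
  statics_cell <- list(slope = 1, twi = 8, wind = 0.5, ph = 6.8,
                       sand = 40, silt = 40, clay = 20)
  tm <- rep(15, 12); pm <- rep(60, 12); sm <- rep(170, 12)
  expect_equal(window_score(tm, pm, sm, statics_cell, crop, 1), 1)

  ## one below-absolute month kills the window
  tm2 <- tm; tm2[3] <- -10
  expect_equal(window_score(tm2, pm, sm, statics_cell, crop, 1), 0)
  expect_equal(window_score(tm2, pm, sm, statics_cell, crop, 4), 1)

  ## the weakest term carries through: membership 0.5 on the temp ramp
  crop2 <- easy_crop(duration = 1, temp = trapezoid(10, 20, 25, 35))
  expect_equal(window_score(rep(15, 12), pm, sm, statics_cell, crop2, 1), 0.5)

  ## kill temperature annuls an otherwise fine window
  crop3 <- easy_crop(duration = 3)
  crop3$kill_temperature <- 16
  expect_equal(window_score(tm, pm, sm, statics_cell, crop3, 1), 0)
})

test_that("pipeline suitability equals the brute-force evaluator", {
  for (sd in c(3, 8)) {
    spec <- world_spec(seed = sd, coarse_shape = c(2, 2), fine_factor = 3,
                       year_range = c(0, 39))
    ter <- generate_terrain(spec)
    soil <- generate_soil(spec, ter)
    statics <- static_grids(ter, soil)
    cl <- generate_climate(spec, ter, snapshot_starts = c(0))
    base <- snapshot_mean(cl$cube, cl$baseline_window[1])
    snap <- delta_downscale(snapshot_mean(cl$cube, 0), base, cl$reference)
    for (cr in generate_crops(2, seed = sd * 11)) {
      fast <- crop_suitability(snap, statics, cr)
      slow <- suitability_brute_force(snap, statics, cr)
      expect_lt(max(abs(fast$values - slow)), 1e-12)
    }
  }
})

test_that("suitability is the maximum over start-month windows", {
  w <- small_world()
  crop <- generate_crops(1, seed = 42)[[1]]
  suit <- crop_suitability(w$snapshot, w$statics, crop)
  cell <- list(r = 3, c = 4)
  st <- w$statics
  statics_cell <- list(slope = st$slope[cell$r, cell$c],
                       twi = st$twi[cell$r, cell$c],
                       wind = st$wind[cell$r, cell$c],
                       ph = st$ph[cell$r, cell$c],
                       sand = st$sand[cell$r, cell$c],
                       silt = st$silt[cell$r, cell$c],
                       clay = st$clay[cell$r, cell$c])
  scores <- sapply(1:12, function(s)
    window_score(w$snapshot$temperature[cell$r, cell$c, ],
                 w$snapshot$precipitation[cell$r, cell$c, ],
                 st$solar[cell$r, cell$c, ], statics_cell, crop, s))
  expect_equal(suit$values[cell$r, cell$c], max(scores))
})

test_that("widening a trapezoid never decreases suitability", {
  w <- small_world()
  crops <- generate_crops(4, seed = 13)
  params <- c("temperature", "precipitation", "slope", "twi", "wind",
              "solar", "ph")
  set.seed(99)
  for (cr in crops) {
    base <- crop_suitability(w$snapshot, w$statics, cr)
    for (p in sample(params, 3)) {
      cr2 <- cr
      t <- cr2[[p]]
      span <- max(t$amax - t$amin, 1)
      cr2[[p]] <- trapezoid(t$amin - 0.3 * span, t$omin - 0.1 * span,
                            t$omax + 0.1 * span, t$amax + 0.3 * span)
      wide <- crop_suitability(w$snapshot, w$statics, cr2)
      expect_true(all(wide$values - base$values >= -1e-12))
    }
  }
})

test_that("a parameter whose membership is 1 everywhere is neutral", {
  w <- small_world()
  cr <- generate_crops(1, seed = 21)[[1]]
  base <- crop_suitability(w$snapshot, w$statics, cr)
  cr2 <- cr
  cr2$twi <- trapezoid(-1e6, -1e5, 1e5, 1e6)   # never binding
  cr3 <- cr2
  cr3$twi <- trapezoid(-2e6, -2e5, 2e5, 2e6)   # still never binding
  m2 <- crop_suitability(w$snapshot, w$statics, cr2)
  m3 <- crop_suitability(w$snapshot, w$statics, cr3)
  expect_identical(m2$values, m3$values)
  ## and the law of the minimum bounds suitability by the static terms
  expect_true(all(base$values <= m2$values + 1e-12))
})

test_that("classification uses left-closed 20 percent bins", {
  expect_equal(as.vector(normalize_classify(c(0.10, 0.20, 0.399, 0.40,
                                              0.799, 0.80, 1.00))),
               c(1L, 2L, 2L, 3L, 4L, 5L, 5L))
  cls <- normalize_classify(matrix(c(0.1, NA, 0.5, 0.95), 2, 2))
  expect_true(is.na(cls[2, 1]))
  expect_equal(attr(cls, "levels"), suitability_classes())
})
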