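test_that("generators are deterministic given the seed", {
  spec <- small_spec(11)
  t1 <- generate_terrain(spec); t2 <- generate_terrain(spec)
  expect_identical(t1, t2)
  s1 <- generate_soil(spec, t1); s2 <- generate_soil(spec, t2)
  expect_identical(s1, s2)
  c1 <- generate_climate(spec, t1, snapshot_starts = c(-149))
  c2 <- generate_climate(spec, t1, snapshot_starts = c(-149))
  expect_identical(c1, c2)
  p1 <- generate_proxy(spec, c1$cube); p2 <- generate_proxy(spec, c1$cube)
  expect_identical(p1, p2)
  expect_identical(generate_crops(3, 5), generate_crops(3, 5))
})

test_that("degenerate grids and windows are rejected", {
  expect_error(world_spec(coarse_shape = c(1, 4)), "each >= 2")
  expect_error(world_spec(ar1_coef = 1), "ar1_coef")
  expect_error(world_spec(year_range = c(10, 5)), "non-empty")
  spec <- world_spec(coarse_shape = c(2, 2), year_range = c(0, 9))
  expect_error(generate_climate(spec, generate_terrain(spec)),
               "shorter than one snapshot window")
})

test_that("flat elevation gives exactly zero slope", {
  expect_equal(slope_from_elevation(matrix(500, 8, 8), 1000),
               matrix(0, 8, 8))
})

test_that("terrain fields decorrelate from elevation without smoothing", {
  ## with no relief organization the auxiliary fields are pure noise:
  ## pooled over seeds, their correlation with elevation is ~0
  rs <- sapply(1:5, function(sd) {
    spec <- world_spec(seed = sd, coarse_shape = c(4, 4), fine_factor = 5,
                       year_range = c(0, 39), terrain_smoothing = 0)
    ter <- generate_terrain(spec)
    c(cor(as.vector(ter$elevation), as.vector(ter$twi)),
      cor(as.vector(ter$elevation), as.vector(ter$wind)))
  })
  expect_lt(abs(mean(rs[1, ])), 0.1)
  expect_lt(abs(mean(rs[2, ])), 0.1)
  ## and at the default smoothing the conditioning is present
  ter <- small_world()$terrain
  expect_lt(cor(as.vector(ter$elevation), as.vector(ter$twi)), -0.3)
})

test_that("soil fractions close to 100 and stay positive", {
  w <- small_world()
  s <- w$soil
  expect_true(all(abs(s$sand + s$silt + s$clay - 100) < 1e-9))
  expect_true(all(s$sand > 0 & s$silt > 0 & s$clay > 0))
  expect_true(all(s$ph >= 0 & s$ph <= 14))
})

test_that("coarse cube is the exact block mean of the latent fine truth", {
  w <- small_world()
  tru <- w$climate$truth[[1]]
  snap <- snapshot_mean(w$climate$cube, tru$window[1])
  for (m in c(1, 6, 12)) {
    expect_lt(max(abs(block_mean(tru$temperature[, , m], 5) -
                        snap$temperature[, , m])), 1e-9)
    expect_lt(max(abs(block_mean(tru$precipitation[, , m], 5) -
                        snap$precipitation[, , m])), 1e-9)
  }
})

test_that("zero variability collapses every year onto the climatology", {
  spec <- world_spec(seed = 3, coarse_shape = c(2, 2), fine_factor = 3,
                     year_range = c(0, 59), trend_per_century = 0,
                     noise_sd_temp = 0, noise_sd_prec = 0)
  ter <- generate_terrain(spec)
  cl <- generate_climate(spec, ter, snapshot_starts = c(0))
  cube <- cl$cube
  for (y in c(1, 30, 60))
    expect_equal(cube$temperature[y, , , ], cube$temperature[1, , , ])
  ## snapshot means equal the reference climatology on the coarse grid
  s0 <- snapshot_mean(cube, 0)
  sref <- snapshot_mean(cube, cl$baseline_window[1])
  expect_equal(s0$temperature, sref$temperature, tolerance = 1e-12)
})

test_that("a linear trend is recovered in first-vs-last snapshot means", {
  spec <- world_spec(seed = 5, coarse_shape = c(2, 2), fine_factor = 3,
                     year_range = c(0, 199), trend_per_century = 1.0,
                     ar1_coef = 0, noise_sd_temp = 0.3, noise_sd_prec = 0)
  ter <- generate_terrain(spec)
  cl <- generate_climate(spec, ter)
  region <- cbind(row = c(1, 1, 2, 2), col = c(1, 2, 1, 2))
  ann <- annual_aggregate(cl$cube, region)
  d_obs <- mean(ann$temperature[181:200]) - mean(ann$temperature[1:20])
  d_exp <- 1.0 * (200 - 20) / 100   # closed form for a linear trend
  ## tolerance: 3 x the standard error implied by the noise settings
  ## (annual sd ~ sqrt(sd^2 + (sd/2)^2/12), windows of 20 years)
  se <- sqrt(2 * (0.3^2 + (0.15^2) / 12) / 20)
  expect_lt(abs(d_obs - d_exp), 3 * se)
})

test_that("precipitation never goes negative across seeded worlds", {
  for (sd in 1:10) {
    spec <- world_spec(seed = sd, coarse_shape = c(2, 2), fine_factor = 3,
                       year_range = c(0, 39), noise_sd_prec = 40)
    cl <- generate_climate(spec, generate_terrain(spec))
    expect_true(all(cl$cube$precipitation >= 0))
  }
})

test_that("proxy with no distortion equals the source series", {
  spec <- world_spec(seed = 9, coarse_shape = c(2, 2), fine_factor = 3,
                     year_range = c(0, 99), proxy_lag = 0,
                     proxy_smoothing = 1, proxy_noise_sd = 0,
                     proxy_sample_spacing = 4)
  cl <- generate_climate(spec, generate_terrain(spec))
  rec <- generate_proxy(spec, cl$cube, n_sites = 1)[[1]]
  region <- cbind(row = c(1, 1, 2, 2), col = c(1, 2, 1, 2))
  ann <- annual_aggregate(cl$cube, region)
  expect_equal(rec$samples$temperature,
               ann$temperature[match(rec$samples$year, ann$year)])
  expect_equal(rec$samples$precipitation,
               ann$precipitation[match(rec$samples$year, ann$year)])
})

test_that("proxy lag shows up as the cross-correlation peak", {
  spec <- world_spec(seed = 2, coarse_shape = c(2, 2), fine_factor = 3,
                     year_range = c(0, 399), proxy_lag = 30,
                     proxy_smoothing = 5, proxy_noise_sd = 0.05,
                     proxy_sample_spacing = 1, ar1_coef = 0.9,
                     trend_per_century = 0)
  cl <- generate_climate(spec, generate_terrain(spec))
  rec <- generate_proxy(spec, cl$cube, n_sites = 1)[[1]]
  region <- cbind(row = c(1, 1, 2, 2), col = c(1, 2, 1, 2))
  ann <- annual_aggregate(cl$cube, region)
  pr <- suppressWarnings(interpolate_record(rec, ann$year))
  common <- pr$year
  src <- ann$temperature[match(common, ann$year)]
  lags <- 0:60
  cc <- sapply(lags, function(L) {
    n <- length(common) - L
    cor(pr$temperature[(L + 1):length(common)], src[1:(length(common) - L)])
  })
  expect_lt(abs(lags[which.max(cc)] - 30), 1 + 5 / 2)
})

test_that("doubling the sample spacing roughly halves the sample count", {
  count_for <- function(spacing, sd) {
    spec <- world_spec(seed = sd, coarse_shape = c(2, 2), fine_factor = 3,
                       year_range = c(0, 599), proxy_sample_spacing = spacing,
                       proxy_lag = 0)
    cl <- generate_climate(spec, generate_terrain(spec))
    nrow(generate_proxy(spec, cl$cube, n_sites = 1)[[1]]$samples)
  }
  n1 <- mean(sapply(1:4, function(sd) count_for(5, sd)))
  n2 <- mean(sapply(1:4, function(sd) count_for(10, sd)))
  ## Poisson-scale tolerance around the 2:1 expectation
  expect_lt(abs(n1 / n2 - 2), 0.5)
})

test_that("an oversized proxy lag is rejected", {
  spec <- world_spec(seed = 1, coarse_shape = c(2, 2), fine_factor = 3,
                     year_range = c(0, 59), proxy_lag = 40)
  cl <- generate_climate(spec, generate_terrain(spec))
  expect_error(generate_proxy(spec, cl$cube), "half the series length")
})

test_that("generated crops satisfy the range ordering for every parameter", {
  crops <- generate_crops(20, seed = 4)
  for (cr in crops) {
    for (p in c("temperature", "precipitation", "slope", "twi", "wind",
                "solar", "ph")) {
      t <- cr[[p]]
      expect_true(t$amin <= t$omin && t$omin <= t$omax && t$omax <= t$amax)
    }
    expect_true(cr$duration_months >= 1 && cr$duration_months <= 12)
  }
})

test_that("the sentinel crop scores 1 on its construction cells", {
  w <- small_world()
  cells <- cbind(row = c(2, 3, 2), col = c(2, 2, 3))
  sen <- sentinel_crop(w$snapshot, w$statics, cells)
  suit <- crop_suitability(w$snapshot, w$statics, sen)
  expect_equal(suit$values[cells], rep(1, nrow(cells)))
  ## a cell pushed outside an absolute range year-round scores 0
  statics2 <- w$statics
  statics2$ph[1, 1] <- sen$ph$amax + 1
  suit2 <- crop_suitability(w$snapshot, statics2, sen)
  expect_identical(suit2$values[1, 1], 0)
})
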