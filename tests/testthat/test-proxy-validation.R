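fake_record <- function(id, row, col, years, tvals = NULL, pvals = NULL) {
  list(site_id = id, row = row, col = col,
       samples = data.frame(
         year = years,
         temperature = tvals %||% (10 + 0.01 * years),
         precipitation = pvals %||% (600 + 0.1 * years)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

fake_similarity <- function(values, nr = 4, nc = 4) {
  structure(list(values = matrix(values, nr, nc), site = c(1L, 1L),
                 weights = c(temperature = 1, precipitation = 1),
                 geom = ps_geom(nr, nc)), class = "ps_similarity")
}

test_that("record selection applies both strict thresholds", {
  win <- c(0, 100)
  recs <- structure(list(
    fake_record("keep", 1, 1, seq(0, 100, by = 15)),      # 7 dates
    fake_record("lowsim", 2, 2, seq(0, 100, by = 15)),
    fake_record("fewdates", 3, 3, seq(0, 100, by = 20)),  # exactly 6? no: 6
    fake_record("edge-sim", 4, 4, seq(0, 100, by = 15))),
    class = "ps_proxy_records")
  sim <- fake_similarity(0.75)
  sim$values[2, 2] <- 0.4
  sim$values[4, 4] <- 0.70          # exactly at the threshold: excluded
  ## 6 dates = min_dates + 1 passes; exactly 5 would not
  recs[[3]]$samples <- recs[[3]]$samples[1:5, ]   # exactly 5 dates
  kept <- select_records(recs, sim, 0.7, 5, win)
  expect_equal(vapply(kept, function(r) r$site_id, ""), "keep")
})

test_that("records outside the similarity map are excluded with a warning", {
  recs <- structure(list(fake_record("out", 9, 9, seq(0, 100, 10))),
                    class = "ps_proxy_records")
  expect_warning(kept <- select_records(recs, fake_similarity(0.9), 0.7, 5,
                                        c(0, 100)),
                 "outside the similarity map")
  expect_length(kept, 0)
})

test_that("record interpolation is linear, node-exact and never extrapolates", {
  rec <- fake_record("r", 1, 1, c(0, 10), tvals = c(10, 20),
                     pvals = c(100, 200))
  out <- interpolate_record(rec, c(0, 5, 10))
  expect_equal(out$temperature, c(10, 15, 20))
  expect_equal(out$precipitation, c(100, 150, 200))
  expect_warning(out2 <- interpolate_record(rec, c(-5, 5, 12)),
                 "outside the sample span")
  expect_equal(out2$year, 5)
  expect_equal(attr(out2, "dropped_years"), c(-5, 12))
  single <- fake_record("s", 1, 1, 3)
  expect_error(interpolate_record(single, 3), "single sample")
})

test_that("composite series averages aligned records", {
  a <- data.frame(year = 1:3, temperature = c(10, 10, 10),
                  precipitation = c(100, 100, 100))
  b <- data.frame(year = 1:3, temperature = c(20, 20, 20),
                  precipitation = c(300, 300, 300))
  cmp <- composite_series(list(a, b))
  expect_equal(cmp$temperature, rep(15, 3))
  expect_equal(cmp$precipitation, rep(200, 3))
  expect_identical(composite_series(list(a)), a)
  b_bad <- b; b_bad$year <- 2:4
  expect_error(composite_series(list(a, b_bad)), "common year grid")
})

test_that("an exact-copy proxy validates at distance zero", {
  spec <- world_spec(seed = 4, coarse_shape = c(2, 2), fine_factor = 3,
                     year_range = c(0, 299))
  cl <- generate_climate(spec, generate_terrain(spec))
  ## a record that copies the regional series at every single year
  region <- cbind(row = c(1, 1, 2, 2), col = c(1, 2, 1, 2))
  ann <- annual_aggregate(cl$cube, region)
  recs <- structure(list(list(site_id = "copy", row = 4L, col = 4L,
                              samples = ann)),
                    class = "ps_proxy_records")
  sim <- similarity_index(cl$reference, c(4, 4))
  rep <- compare_simulation_proxy(cl$cube, recs, sim, pattern = "symmetric2",
                                  window = c(0, 299))
  expect_lt(rep$temperature$normalized_distance, 1e-9)
  expect_lt(rep$precipitation$normalized_distance, 1e-9)
  ## near-diagonal path for a lag-free copy
  off <- abs(rep$temperature$alignment$path[, 1] -
               rep$temperature$alignment$path[, 2])
  expect_lte(median(off), 1)
  expect_equal(rep$phase_agreement, 1)
})

test_that("a known proxy lag is recovered by the alignment path", {
  hits <- 0
  for (sd in 1:5) {
    spec <- world_spec(seed = sd, coarse_shape = c(2, 2), fine_factor = 3,
                       year_range = c(0, 199), proxy_lag = 3,
                       proxy_smoothing = 5, proxy_noise_sd = 0.2,
                       proxy_sample_spacing = 1, ar1_coef = 0.8,
                       trend_per_century = 0)
    cl <- generate_climate(spec, generate_terrain(spec))
    rec <- generate_proxy(spec, cl$cube, n_sites = 1)[[1]]
    region <- cbind(row = c(1, 1, 2, 2), col = c(1, 2, 1, 2))
    ann <- annual_aggregate(cl$cube, region)
    pr <- suppressWarnings(interpolate_record(rec, ann$year))
    src <- ann$temperature[match(pr$year, ann$year)]
    al <- dtw_align(zscore(src), zscore(pr$temperature), "symmetric2")
    if (abs(path_offset(al) - 3) <= 1) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("an unrelated proxy scores worse than a lagged copy", {
  worse <- 0; n_trials <- 8
  for (sd in seq_len(n_trials)) {
    spec <- world_spec(seed = sd, coarse_shape = c(2, 2), fine_factor = 3,
                       year_range = c(0, 149), proxy_lag = 3,
                       proxy_smoothing = 5, proxy_noise_sd = 0.1,
                       proxy_sample_spacing = 1, ar1_coef = 0.8)
    cl <- generate_climate(spec, generate_terrain(spec))
    rec <- generate_proxy(spec, cl$cube, n_sites = 1)[[1]]
    region <- cbind(row = c(1, 1, 2, 2), col = c(1, 2, 1, 2))
    ann <- annual_aggregate(cl$cube, region)
    pr <- suppressWarnings(interpolate_record(rec, ann$year))
    src <- zscore(ann$temperature[match(pr$year, ann$year)])
    lagged <- dtw_align(src, zscore(pr$temperature), "symmetric2")
    set.seed(1000 + sd)
    rnd <- zscore(as.numeric(arima.sim(list(ar = 0.8), length(src))))
    random <- dtw_align(src, rnd, "symmetric2")
    if (random$normalized_distance > lagged$normalized_distance)
      worse <- worse + 1
  }
  expect_gte(worse, n_trials - 1)
})

test_that("an empty selection raises an explicit error", {
  w <- small_world()
  recs <- generate_proxy(w$spec, w$climate$cube, n_sites = 2)
  sim <- similarity_index(w$climate$reference, c(3, 3))
  sim$values[] <- 0.1
  expect_error(
    compare_simulation_proxy(w$climate$cube, recs, sim,
                             window = c(-199, 100)),
    "no proxy record passes")
})
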