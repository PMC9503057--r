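test_that("simulators are bit-identical under a repeated seed", {
  sc <- synthetic_scenario(n_trees = 6, seed = 7)
  c1 <- simulate_daily_temperature(sc)
  c2 <- simulate_daily_temperature(sc)
  expect_identical(c1$data, c2$data)
  s1 <- simulate_ring_dataset(sc, c1)
  s2 <- simulate_ring_dataset(sc, c2)
  expect_identical(s1$trw$wide, s2$trw$wide)
  expect_identical(s1$reflectance$wide, s2$reflectance$wide)
  expect_identical(s1$trees, s2$trees)
})

test_that("noise-free climate is the exact seasonal curve", {
  sc <- synthetic_scenario(seed = 3,
                           climate = list(annual_mean = 5, amplitude = 10,
                                          harmonic2 = 0.1, trough_doy = 15,
                                          daily_ar = 0.5, daily_sd = 0,
                                          interannual_sd = 0))
  cl <- simulate_daily_temperature(sc, years = 2000:2001)
  d <- cl$data$date
  yr <- as.integer(format(d, "%Y"))
  theta <- 2 * pi * as.numeric(d - (as.Date(sprintf("%d-01-01", yr)) + 14)) /
    365.25
  expected <- 5 - 10 * cos(theta) - 1 * cos(2 * theta)
  expect_equal(cl$data$tmean, round(expected, 3), tolerance = 1e-9)
})

test_that("simulated climatology matches mountain-valley normals", {
  sc <- synthetic_scenario(seed = 11,
                           climate = list(annual_mean = 6, amplitude = 11,
                                          harmonic2 = 0.1, trough_doy = 15,
                                          daily_ar = 0.7, daily_sd = 3.5,
                                          interannual_sd = 0.6))
  cl <- simulate_daily_temperature(sc, years = 1950:2049)
  mo <- as.integer(format(cl$data$date, "%m"))
  jan <- mean(cl$data$tmean[mo == 1])
  jul <- mean(cl$data$tmean[mo == 7])
  expect_gt(jan, -7);  expect_lt(jan, -4.5)
  expect_gt(jul, 15.4); expect_lt(jul, 17.6)
  expect_gt(mean(cl$data$tmean), 4.5)
  expect_lt(mean(cl$data$tmean), 7.5)
})

test_that("raw ring series inherit the prescribed temporal memory", {
  sc <- synthetic_scenario(seed = 21)   # default stand, ar_phi = 0.75
  cl <- simulate_daily_temperature(sc)
  sim <- simulate_ring_dataset(sc, cl)
  ac1 <- vapply(ringclim:::series_list(sim$trw), function(s) {
    v <- s$values
    cor(v[-1], v[-length(v)])
  }, 0)
  expect_gt(mean(ac1), 0.6)
  expect_lt(mean(ac1), 0.9)
})

test_that("default scenario reproduces observed chronology statistics", {
  sc <- synthetic_scenario(seed = 31)
  cl <- simulate_daily_temperature(sc)
  sim <- simulate_ring_dataset(sc, cl)
  ind <- detrend_dataset(sim$trw)
  re <- rbar_eps(ind, years = sc$years)
  expect_gt(re$rbar, 0.15)
  expect_lt(re$rbar, 0.35)
  expect_gt(re$eps, 0.85)
})

test_that("reflectance inverts exactly through the BI transform", {
  sc <- synthetic_scenario(n_trees = 4, seed = 41)
  cl <- simulate_daily_temperature(sc)
  sim <- simulate_ring_dataset(sc, cl)
  refl <- sim$reflectance$wide
  expect_true(all(refl[!is.na(refl)] >= 0 & refl[!is.na(refl)] <= 255))
  bi <- build_bi(sim$reflectance)
  ok <- !is.na(refl)
  expect_equal(bi$wide[ok], 2.56 - refl[ok] / 100, tolerance = 1e-12)
})

test_that("a window outside the climate record is refused", {
  sc <- synthetic_scenario(n_trees = 3, seed = 51)
  cl <- simulate_daily_temperature(sc, years = 1990:2019)
  sc_bad <- synthetic_scenario(n_trees = 3, seed = 51, years = 1978:2019)
  expect_error(simulate_ring_dataset(sc_bad, cl), "not covered")
})

test_that("without an injected signal, window recovery is at chance", {
  hits <- vapply(1:5, function(i) {
    sc <- synthetic_scenario(seed = 700 + i, target_r = 0)
    cl <- simulate_daily_temperature(sc)
    sim <- simulate_ring_dataset(sc, cl)
    ind <- detrend_dataset(sim$trw)
    crn <- truncate_common_period(build_chronology(ind), growth_years(cl))
    grid <- season_grid(cl, years = crn$year,
                        widths = c(21, 41, 61, 81, 101))
    b <- find_best_window(crn, grid, n_boot = 200, seed = 800 + i)
    !is.null(b) &&
      abs(b$start - sc$signal_start) <= 10 &&
      abs(b$width - sc$signal_width) <= 15
  }, TRUE)
  expect_lte(sum(hits), 1)
})

test_that("the injected signal window is recovered up to ridge ambiguity", {
  # recovered best window should intersect the true window's day span in
  # the clear majority of replicates
  hits <- vapply(1:10, function(i) {
    rep <- pipeline_replicate(1000 + i, 2000 + i, n_boot = 500)
    b <- rep$best
    !is.null(b) &&
      b$start <= rep$truth$signal_start + rep$truth$signal_width - 1 &&
      b$start + b$width - 1 >= rep$truth$signal_start
  }, TRUE)
  expect_gte(mean(hits), 0.7)
})
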