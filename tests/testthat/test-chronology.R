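test_that("biweight mean matches symmetry and the IRLS oracle", {
  expect_equal(biweight_mean(c(1, 1, 1)), 1)
  expect_equal(biweight_mean(c(0.8, 1.0, 1.2)), 1)
  expect_equal(biweight_mean(c(1.3, 0.9)), 1.1)  # n <= 2: arithmetic mean
  expect_error(biweight_mean(numeric(0)), "empty")

  b <- biweight_mean(c(1, 1, 1, 1, 10))
  expect_gt(b, 0.99)
  expect_lt(b, 1.05)
  expect_equal(b, oracle_biweight(c(1, 1, 1, 1, 10)), tolerance = 1e-6)

  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1), 1, 0.2)
    if (i %% 4 == 0) x <- c(x, 5)  # occasional gross outlier
    expect_equal(biweight_mean(x), oracle_biweight(x), tolerance = 1e-6)
    expect_gte(biweight_mean(x), min(x))
    expect_lte(biweight_mean(x), max(x))
  }
})

test_that("chronology aggregation needs overlap and respects identity", {
  m <- cbind(A = c(1.1, 0.9, 1.0, 1.2), B = c(1.1, 0.9, 1.0, 1.2))
  rownames(m) <- 2000:2003
  crn <- build_chronology(m)
  expect_equal(crn$index, c(1.1, 0.9, 1.0, 1.2))
  expect_equal(crn$depth, rep(2, 4))

  disj <- matrix(NA_real_, 8, 2, dimnames = list(2000:2007, c("A", "B")))
  disj[1:4, 1] <- 1
  disj[5:8, 2] <- 1
  expect_error(build_chronology(disj), "overlap")
})

test_that("chronology converges on the common signal as trees are added", {
  set.seed(77)
  n_yr <- 60
  signal <- rnorm(n_yr)
  make <- function(n_series) {
    m <- sapply(seq_len(n_series),
                function(i) 1 + 0.1 * signal + rnorm(n_yr, 0, 0.25))
    rownames(m) <- seq_len(n_yr) + 1950
    cor(build_chronology(m)$index, signal)
  }
  expect_gt(make(40), make(4))
})

test_that("mean sensitivity has its closed-form and invariance properties", {
  expect_equal(mean_sensitivity(rep(2.5, 20)), 0)
  expect_equal(mean_sensitivity(rep(c(1, 3), 10)), 1)
  x <- rlnorm(50, 0, 0.3)
  expect_equal(mean_sensitivity(3.7 * x), mean_sensitivity(x))
  expect_error(mean_sensitivity(c(1, 0, 0, 1)), "sum to zero")
  # same absolute spread on a higher base level -> lower sensitivity,
  # the reason BI chronologies show low MS
  set.seed(88)
  dev <- rnorm(100, 0, 0.1)
  expect_lt(mean_sensitivity(2.2 + dev), mean_sensitivity(1.0 + dev))
})

test_that("rbar and EPS follow their closed forms", {
  expect_equal(eps_from_rbar(10, 0.3), 3 / 3.7)
  m <- cbind(A = rnorm(30, 1, 0.1))
  m <- cbind(m, B = m[, 1], C = m[, 1])
  rownames(m) <- 1981:2010
  re <- rbar_eps(m)
  expect_equal(re$rbar, 1)
  expect_equal(re$eps, 1)
  # monotone in rbar and in mean depth
  rb <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(vapply(rb, eps_from_rbar, 0, n_bar = 10)) > 0))
  nn <- 2:30
  expect_true(all(diff(vapply(nn, eps_from_rbar, 0, rbar = 0.3)) > 0))
})

test_that("crossdating passes synchronized series and flags a shifted one", {
  set.seed(99)
  n_yr <- 100
  years <- 1920 + seq_len(n_yr)
  signal <- rlnorm(n_yr, 0, 0.25)
  rows <- lapply(1:8, function(i) {
    v <- pmax(signal * rlnorm(n_yr, 0, 0.08), 0.05)
    data.frame(series_id = sprintf("S%02d", i), year = years,
               value = round(v, 3))
  })
  good <- ring_data(do.call(rbind, rows), "TRW")
  cd <- crossdating_check(good)
  expect_false(any(cd$flag))

  # shift one series by +1 year: its segments lose sync with the master
  rows[[1]]$year <- rows[[1]]$year + 1L
  shifted <- ring_data(do.call(rbind, rows), "TRW")
  cd2 <- crossdating_check(shifted)
  expect_gte(sum(cd2$flag[cd2$series_id == "S01"]), 1)
})

test_that("with two series the leave-one-out master is the other series", {
  set.seed(101)
  years <- 1951:2010
  a <- rlnorm(60, 0, 0.2)
  b <- a * rlnorm(60, 0, 0.05)
  d <- ring_data(rbind(
    data.frame(series_id = "A", year = years, value = a),
    data.frame(series_id = "B", year = years, value = b)), "TRW")
  cd <- crossdating_check(d, seg_len = 40, overlap = 20)
  ia <- to_standard_index(a, spline_fit(a))
  ib <- to_standard_index(b, spline_fit(b))
  seg1 <- cd[cd$series_id == "A", ][1, ]
  idx <- which(years >= seg1$start & years <= seg1$end)
  expect_equal(seg1$r, cor(ia[idx], ib[idx]), tolerance = 1e-9)
})

test_that("common-period truncation clips to climate coverage", {
  crn <- as_chron(1885:2019, rnorm(135, 1, 0.1))
  cl <- make_climate(1978:2019)
  out <- truncate_common_period(crn, cl)
  expect_equal(nrow(out), 42)
  expect_equal(range(out$year), c(1978, 2019))

  full <- truncate_common_period(crn, 1800:2100)
  expect_equal(nrow(full), nrow(crn))
  expect_error(truncate_common_period(crn, 2050:2060), "overlap")
})

test_that("chronology statistics report Table-style descriptors", {
  set.seed(111)
  sc <- synthetic_scenario(n_trees = 12, seed = 112)
  cl <- simulate_daily_temperature(sc)
  sim <- simulate_ring_dataset(sc, cl)
  ind <- detrend_dataset(sim$trw)
  st <- chronology_stats(sim$trw, ind, years = sc$years)
  expect_equal(st$n_series, 12)
  expect_gte(st$length_min, 68)
  expect_lte(st$length_max, 135)
  expect_true(st$rbar > -1 && st$rbar < 1)
  expect_true(st$eps >= 0 && st$eps <= 1)
  expect_gte(st$mean_sens, 0)
  expect_gt(st$auto_corr, 0.3)  # strong temporal memory in raw rings
})
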