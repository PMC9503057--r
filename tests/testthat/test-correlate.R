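test_that("perfect and inverted correlations are certain", {
  set.seed(1)
  x <- rnorm(41)
  b <- bootstrap_pearson(x, x, n_boot = 500, seed = 3)
  expect_equal(b$r, 1)
  expect_true(b$significant)

  b2 <- bootstrap_pearson(x, -x, n_boot = 500, seed = 3)
  expect_equal(b2$r, -1)
  expect_lt(b2$ci_high, 0)
  expect_true(b2$significant)
})

test_that("bootstrap correlation is affine-invariant and seed-deterministic", {
  set.seed(2)
  x <- rnorm(40)
  y <- 0.5 * x + rnorm(40, 0, 0.8)
  b <- bootstrap_pearson(x, y, n_boot = 400, seed = 11)
  bpos <- bootstrap_pearson(x, 3 + 2 * y, n_boot = 400, seed = 11)
  expect_equal(b$r, bpos$r, tolerance = 1e-10)
  expect_equal(b$ci_low, bpos$ci_low, tolerance = 1e-10)
  bneg <- bootstrap_pearson(x, -y, n_boot = 400, seed = 11)
  expect_equal(bneg$r, -b$r, tolerance = 1e-10)

  again <- bootstrap_pearson(x, y, n_boot = 400, seed = 11)
  expect_identical(b$r, again$r)
  expect_identical(b$ci_low, again$ci_low)
  expect_identical(b$ci_high, again$ci_high)
  # CI brackets the point estimate on well-behaved data
  expect_lte(b$ci_low, b$r)
  expect_gte(b$ci_high, b$r)
})

test_that("bootstrap correlation rejects degenerate input", {
  expect_error(bootstrap_pearson(rnorm(20), rnorm(19)), "equal length")
  expect_error(bootstrap_pearson(rep(1, 20), rnorm(20)), "zero variance")
  expect_error(bootstrap_pearson(rnorm(5), rnorm(5)), "at least 10")
})

test_that("grid correlation is reproducible and flags the injected window", {
  sc <- synthetic_scenario(seed = 301)
  cl <- simulate_daily_temperature(sc)
  grid <- season_grid(cl, years = sc$years, widths = c(30, 60, 90))
  j <- which(grid$cells$start == sc$signal_start & grid$cells$width == 60)
  set.seed(302)
  x <- as.numeric(scale(grid$means[, j])) * 0.6 + rnorm(42, 0, 0.8)
  crn <- as_chron(sc$years, 1 + 0.1 * x)

  wc1 <- correlate_grid(crn, grid, n_boot = 300, seed = 9)
  wc2 <- correlate_grid(crn, grid, n_boot = 300, seed = 9)
  expect_identical(wc1$results, wc2$results)

  expect_false(is.null(wc1$best))
  # the best window must carry real signal: near the injected day range
  expect_lt(abs(wc1$best$start - sc$signal_start), 60)

  # constant chronology cannot be correlated
  flat <- as_chron(sc$years, rep(1, 42))
  expect_error(correlate_grid(flat, grid), "zero variance")
  # year mismatch is refused
  short <- as_chron(sc$years[-1], x[-1])
  expect_error(correlate_grid(short, grid), "do not match")
})

test_that("lazy best-window search equals the full grid's best cell", {
  sc <- synthetic_scenario(seed = 401)
  cl <- simulate_daily_temperature(sc)
  grid <- season_grid(cl, years = sc$years, widths = c(21, 45, 70))
  j <- which(grid$cells$start == 200 & grid$cells$width == 45)
  set.seed(402)
  x <- as.numeric(scale(grid$means[, j])) + rnorm(42, 0, 1.1)
  crn <- as_chron(sc$years, x)
  full <- correlate_grid(crn, grid, n_boot = 300, seed = 17)
  lazy <- find_best_window(crn, grid, n_boot = 300, seed = 17)
  expect_false(is.null(full$best))
  expect_equal(lazy$start, full$best$start)
  expect_equal(lazy$width, full$best$width)
  expect_equal(lazy$r, full$best$r, tolerance = 1e-12)
  expect_equal(lazy$ci_low, full$best$ci_low, tolerance = 1e-12)
})

test_that("a noise chronology yields few significant cells", {
  sc <- synthetic_scenario(seed = 501)
  cl <- simulate_daily_temperature(sc)
  grid <- season_grid(cl, years = sc$years, widths = c(25, 55, 85, 115))
  rates <- vapply(1:3, function(i) {
    set.seed(510 + i)
    crn <- as_chron(sc$years, rnorm(42, 1, 0.1))
    wc <- correlate_grid(crn, grid, n_boot = 200, seed = 520 + i)
    mean(wc$results$significant, na.rm = TRUE)
  }, 0)
  # nominal-ish rate; wide bound because cells are strongly dependent
  expect_lt(mean(rates), 0.3)
})

test_that("moving correlation counts windows and applies the critical r", {
  yrs <- 1978:2019
  set.seed(601)
  x <- rnorm(42)
  crn <- as_chron(yrs, x)
  mc <- moving_stability(crn, data.frame(year = yrs, temp = x))
  expect_equal(nrow(mc), 28)          # 42 - 15 + 1
  expect_equal(mc$r, rep(1, 28), tolerance = 1e-12)
  expect_true(all(mc$significant))
  expect_equal(attr(mc, "r_crit"), 0.514, tolerance = 1e-3)

  short <- as_chron(1978:1992, rnorm(15))
  expect_error(moving_stability(short,
                                data.frame(year = 1978:1992, temp = rnorm(15))),
               "more than 15")
})
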