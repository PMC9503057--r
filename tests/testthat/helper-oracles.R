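# Independent oracles and fixture builders shared across test files.

# Straightforward iterated-reweighting implementation of the Tukey biweight
# location (tuning constant 9, unscaled MAD), written independently of the
# package's biweight_mean().
oracle_biweight <- function(x, tol = 1e-12, maxit = 500) {
  loc <- median(x)
  for (i in seq_len(maxit)) {
    s <- 9 * median(abs(x - loc))
    if (s == 0) return(median(x))
    u <- (x - loc) / s
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    new <- sum(w * x) / sum(w)
    if (abs(new - loc) < tol) return(new)
    loc <- new
  }
  loc
}

# random TRW dataset for round-trip / property tests
random_trw <- function(n_series = 4, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_series), function(i) {
    n <- sample(15:60, 1)
    first <- sample(1900:1960, 1)
    data.frame(series_id = sprintf("S%02d", i),
               year = seq.int(first, length.out = n),
               value = round(pmax(rlnorm(n, log(1.5), 0.4), 0.05), 3))
  })
  ring_data(do.call(rbind, rows), proxy = "TRW")
}

# complete daily climate over calendar years, simple seasonal cycle
make_climate <- function(years, temp_fun = NULL, seed = 1) {
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  if (is.null(temp_fun)) {
    set.seed(seed)
    doy <- as.integer(format(dates, "%j"))
    tmean <- 5 - 11 * cos(2 * pi * (doy - 15) / 365.25) + rnorm(length(dates))
  } else {
    tmean <- temp_fun(dates)
  }
  df <- data.frame(date = format(dates), tmean = tmean)
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  read_daily_climate(path, station_id = "test")
}

# wrap a bare index series as a chronology object
as_chron <- function(years, index, depth = 50) {
  structure(data.frame(year = as.integer(years), index = index,
                       depth = depth),
            class = c("chronology", "data.frame"),
            proxy = "TRW", type = "residual")
}

# one full synthetic pipeline replicate: returns recovered best window + truth
pipeline_replicate <- function(sim_seed, boot_seed, n_boot = 1000, ...) {
  sc <- synthetic_scenario(seed = sim_seed, ...)
  cl <- simulate_daily_temperature(sc)
  sim <- simulate_ring_dataset(sc, cl)
  ind <- detrend_dataset(sim$trw)
  crn <- truncate_common_period(build_chronology(ind), growth_years(cl))
  grid <- season_grid(cl, years = crn$year)
  list(best = find_best_window(crn, grid, n_boot = n_boot, seed = boot_seed),
       truth = sim$truth)
}
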