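#' Define a synthetic study scenario
#'
#' Bundles every generative parameter for the paired climate/ring simulators:
#' a stand of `n_trees` cored trees whose annual growth indices carry (i) a
#' climate signal equal to the standardized mean temperature of one known
#' cumulative window, (ii) a shared stand-level AR(1) disturbance component
#' and (iii) idiosyncratic AR(1) noise per tree; raw ring widths are the
#' index times a Hugershoff-shaped age curve (jittered per tree). Latewood
#' blue reflectance is generated the same way on its own (late-season) signal
#' window and mapped through the inverse of the blue-intensity transform, so
#' the analysis-side transform recovers the generated BI exactly.
#'
#' The signal strength is specified as `target_r`, the intended population
#' correlation between the *chronology-level* residual index and the true
#' window's mean temperature; the per-tree regression coefficient `beta` is
#' derived from it via [signal_beta()]. Defaults describe a spruce stand of
#' 50 cores, series lengths 68--135 years ending in 2019, lag-1 index memory
#' 0.75, and a mountain-valley temperature climatology (annual mean 4.8
#' degrees C, January around -6, July around 14).
#'
#' @param n_trees number of cored trees, default 50.
#' @param years analysis years (climate coverage), default `1978:2019`.
#' @param length_range min/max series length in years, default `c(68, 135)`.
#' @param elevation site label stamped on the tree table, default `"high"`.
#' @param signal_start,signal_width the injected window for ring growth, as a
#'   season-day index ([season_index()]) and width in days; default Dec 1 of
#'   the previous year, 60 days.
#' @param target_r intended population correlation at chronology level,
#'   default 0.55.
#' @param ar_phi AR(1) coefficient of both noise components, default 0.75.
#' @param sd_shared,sd_idio stationary standard deviations of the shared and
#'   idiosyncratic index noise, defaults 0.09 and 0.17.
#' @param age_curve Hugershoff parameters (a, b, c, d) of the mean ring-width
#'   age curve in mm, jittered per tree.
#' @param age_jitter_sd lognormal sd of the per-tree jitter on `a` and `d`.
#' @param dbh_base diameter (mm) already present inside the innermost ring
#'   (pith offset plus bark allowance) when accumulating tree DBH.
#' @param trw_floor minimum ring width in mm, default 0.05.
#' @param climate list of climatology parameters: `annual_mean`, `amplitude`
#'   (first-harmonic half-range), `harmonic2` (second-harmonic fraction of
#'   `amplitude`, deepens winter), `trough_doy` (coldest day of year),
#'   `daily_ar`, `daily_sd` (stationary sd of daily AR(1) noise),
#'   `interannual_sd` (sd of calendar-year offsets), all in degrees C where
#'   applicable.
#' @param bi list for the blue-intensity channel: `curve` (Hugershoff
#'   parameters of the BI age curve, unitless), `signal_start`,
#'   `signal_width` (default Aug 15 of the ring year, 59 days), `target_r`,
#'   `sd_shared`, `sd_idio`.
#' @param seed default master seed used by the simulators.
#' @return list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_trees = 50,
                               years = 1978:2019,
                               length_range = c(68, 135),
                               elevation = "high",
                               signal_start = season_index(12, 1, previous = TRUE),
                               signal_width = 60,
                               target_r = 0.55,
                               ar_phi = 0.75,
                               sd_shared = 0.09,
                               sd_idio = 0.17,
                               age_curve = c(a = 0.22, b = 0.9, c = 0.04, d = 1.1),
                               age_jitter_sd = 0.15,
                               dbh_base = 40,
                               trw_floor = 0.05,
                               climate = list(annual_mean = 4.8, amplitude = 10,
                                              harmonic2 = 0.1, trough_doy = 15,
                                              daily_ar = 0.7, daily_sd = 3.5,
                                              interannual_sd = 0.6),
                               bi = list(curve = c(a = 0.05, b = 0.5,
                                                   c = 0.005, d = 2.0),
                                         signal_start = season_index(8, 15, previous = FALSE),
                                         signal_width = 59,
                                         target_r = 0.55,
                                         sd_shared = 0.02,
                                         sd_idio = 0.045),
                               seed = 1) {
  stopifnot(n_trees >= 2, length(years) >= 2, all(diff(years) == 1L),
            length_range[1] >= 2, length_range[2] >= length_range[1],
            signal_width >= 1,
            signal_start + signal_width - 1 <= SEASON_LEN,
            abs(target_r) < 1, abs(ar_phi) < 1,
            sd_shared >= 0, sd_idio >= 0, trw_floor > 0)
  structure(list(n_trees = n_trees, years = as.integer(years),
                 length_range = as.integer(length_range),
                 elevation = elevation,
                 signal_start = as.integer(signal_start),
                 signal_width = as.integer(signal_width),
                 target_r = target_r, ar_phi = ar_phi,
                 sd_shared = sd_shared, sd_idio = sd_idio,
                 age_curve = age_curve, age_jitter_sd = age_jitter_sd,
                 dbh_base = dbh_base, trw_floor = trw_floor,
                 climate = climate, bi = bi, seed = seed),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("<synthetic_scenario> %d trees (%s), years %d-%d\n",
              x$n_trees, x$elevation, min(x$years), max(x$years)))
  cat(sprintf("  growth signal: %s, target chronology r = %.2f\n",
              window_label(x$signal_start, x$signal_width), x$target_r))
  cat(sprintf("  BI signal: %s, target r = %.2f\n",
              window_label(x$bi$signal_start, x$bi$signal_width),
              x$bi$target_r))
  invisible(x)
}

#' Per-tree signal coefficient for a target chronology correlation
#'
#' After prewhitening, the chronology index is approximately
#' `beta * z + innovations` with innovation variance
#' `c2 = (1 - phi^2) * (sd_shared^2 + sd_idio^2 / n_trees)` (the
#' idiosyncratic part averages down with stand size, the shared part does
#' not). Solving `r = beta / sqrt(beta^2 + c2)` for `beta` gives
#' `beta = r * sqrt(c2) / sqrt(1 - r^2)`.
#'
#' @param target_r intended population correlation between chronology and
#'   window temperature, `|r| < 1`.
#' @param ar_phi,sd_shared,sd_idio,n_trees noise structure of the scenario.
#' @return the regression coefficient `beta` applied to the standardized
#'   window temperature in each tree's index.
#' @export
signal_beta <- function(target_r, ar_phi, sd_shared, sd_idio, n_trees) {
  stopifnot(abs(target_r) < 1)
  c2 <- (1 - ar_phi^2) * (sd_shared^2 + sd_idio^2 / n_trees)
  target_r * sqrt(c2) / sqrt(1 - target_r^2)
}

# stationary AR(1) path of length n with stationary sd `sds`
ar1_path <- function(n, phi, sds) {
  if (sds == 0 || n == 0L) return(numeric(n))
  innov <- rnorm(n, 0, sds * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = rnorm(1, 0, sds)))
}

#' Simulate a daily mean-temperature record
#'
#' Daily temperature = annual mean + seasonal cycle + calendar-year offset +
#' AR(1) daily weather noise. The seasonal cycle is a cosine with trough at
#' `trough_doy` (mid-January by default) plus a second harmonic
#' (`harmonic2 * amplitude`) that deepens winter relative to a pure
#' sinusoid, matching mountain-valley climatologies where the annual mean
#' sits closer to the summer maximum than halfway. Deterministic given
#' `seed`.
#'
#' @param scenario a [synthetic_scenario()].
#' @param years growth years to cover; the record spans January 1 of
#'   `min(years) - 1` (so previous-June windows are available) through
#'   December 31 of `max(years)`. Defaults to `scenario$years`.
#' @param seed RNG seed; defaults to `scenario$seed`.
#' @return a `daily_climate`.
#' @export
simulate_daily_temperature <- function(scenario, years = scenario$years,
                                       seed = scenario$seed) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  cl <- scenario$climate
  dates <- seq(as.Date(sprintf("%d-01-01", min(years) - 1L)),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  yr <- as.integer(format(dates, "%Y"))
  # phase measured from the trough day of each calendar year
  trough <- as.Date(sprintf("%d-01-01", yr)) + (cl$trough_doy - 1L)
  theta <- 2 * pi * as.numeric(dates - trough) / 365.25
  seasonal <- -cl$amplitude * cos(theta) -
    cl$harmonic2 * cl$amplitude * cos(2 * theta)
  with_seed(seed, {
    ye <- rnorm(length(unique(yr)), 0, cl$interannual_sd)
    names(ye) <- as.character(unique(yr))
    noise <- ar1_path(length(dates), cl$daily_ar, cl$daily_sd)
    tmean <- cl$annual_mean + seasonal + unname(ye[as.character(yr)]) + noise
    daily_climate(dates, round(tmean, 3),
                  station_id = sprintf("synthetic-%s", scenario$elevation))
  })
}

# mean temperature of the scenario's (start,width) window per growth year
signal_window_means <- function(climate, years, start, width) {
  temp <- climate$data$tmean
  names(temp) <- format(climate$data$date)
  vapply(years, function(y) {
    d <- season_dates(y)[start:(start + width - 1L)]
    v <- unname(temp[format(d)])
    if (anyNA(v))
      stop("signal window not covered by climate record in growth year ", y)
    mean(v)
  }, 0)
}

hugershoff_curve <- function(t, p) {
  p[["a"]] * t^p[["b"]] * exp(-p[["c"]] * t) + p[["d"]]
}

#' Simulate a multi-tree ring dataset with a known injected climate signal
#'
#' Generates, for each tree: ring widths `TRW_t = age_curve(t) * index_t`
#' (floored at `trw_floor`) where
#' `index_t = 1 + beta * z_t + u_t + e_it`, with `z` the standardized mean
#' temperature of the scenario's signal window (zero outside the climate
#' years), `u` a shared stand-level AR(1) component and `e` idiosyncratic
#' AR(1) noise; a coring-year DBH accumulated from the ring sums plus
#' `dbh_base`; and a latewood blue-reflectance series built the same way on
#' the BI signal window and passed through the inverse blue-intensity
#' transform. Deterministic given `seed`.
#'
#' @param scenario a [synthetic_scenario()].
#' @param climate a `daily_climate` covering the scenario's signal windows
#'   (e.g. from [simulate_daily_temperature()]).
#' @param seed RNG seed; defaults to `scenario$seed`.
#' @return list of class `ring_sim`: `trw` (`ring_data`, TRW, with tree
#'   table), `reflectance` (`ring_data`, raw 0--255), `trees`, and `truth`
#'   (list with the injected `signal_start`, `signal_width`, `beta`,
#'   `bi_signal_start`, `bi_signal_width`, `bi_beta`, `seed`).
#' @export
simulate_ring_dataset <- function(scenario, climate, seed = scenario$seed) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(climate, "daily_climate"))
  yrs <- scenario$years
  wm <- signal_window_means(climate, yrs, scenario$signal_start,
                            scenario$signal_width)
  z <- as.numeric(scale(wm))
  wm_bi <- signal_window_means(climate, yrs, scenario$bi$signal_start,
                               scenario$bi$signal_width)
  z_bi <- as.numeric(scale(wm_bi))
  beta <- signal_beta(scenario$target_r, scenario$ar_phi,
                      scenario$sd_shared, scenario$sd_idio, scenario$n_trees)
  beta_bi <- signal_beta(scenario$bi$target_r, scenario$ar_phi,
                         scenario$bi$sd_shared, scenario$bi$sd_idio,
                         scenario$n_trees)
  last <- max(yrs)
  with_seed(seed, {
    lens <- sample(seq.int(scenario$length_range[1L],
                           scenario$length_range[2L]),
                   scenario$n_trees, replace = TRUE)
    span_first <- last - max(lens) + 1L
    all_years <- span_first:last
    zfull <- zfull_bi <- numeric(length(all_years))
    zfull[match(yrs, all_years)] <- z
    zfull_bi[match(yrs, all_years)] <- z_bi
    u <- ar1_path(length(all_years), scenario$ar_phi, scenario$sd_shared)
    u_bi <- ar1_path(length(all_years), scenario$ar_phi,
                     scenario$bi$sd_shared)

    pre <- toupper(substr(scenario$elevation, 1L, 1L))
    trw_rows <- refl_rows <- vector("list", scenario$n_trees)
    trees <- data.frame(series_id = sprintf("%s%03d", pre,
                                            seq_len(scenario$n_trees)),
                        dbh_mm = NA_real_, elevation = scenario$elevation)
    for (i in seq_len(scenario$n_trees)) {
      n <- lens[i]
      t_idx <- seq_len(n)
      years_i <- seq.int(last - n + 1L, last)
      pos <- match(years_i, all_years)
      ac <- scenario$age_curve
      ac[["a"]] <- ac[["a"]] * exp(rnorm(1, 0, scenario$age_jitter_sd))
      ac[["d"]] <- ac[["d"]] * exp(rnorm(1, 0, scenario$age_jitter_sd))
      curve <- hugershoff_curve(t_idx, ac)
      e <- ar1_path(n, scenario$ar_phi, scenario$sd_idio)
      index <- 1 + beta * zfull[pos] + u[pos] + e
      trw <- pmax(curve * index, scenario$trw_floor)
      trees$dbh_mm[i] <- scenario$dbh_base + 2 * sum(trw)

      bc <- scenario$bi$curve
      bc[["d"]] <- bc[["d"]] * exp(rnorm(1, 0, scenario$age_jitter_sd / 3))
      bcurve <- hugershoff_curve(t_idx, bc)
      e_bi <- ar1_path(n, scenario$ar_phi, scenario$bi$sd_idio)
      index_bi <- 1 + beta_bi * zfull_bi[pos] + u_bi[pos] + e_bi
      bi <- pmin(pmax(bcurve * index_bi, 0.01), 2.56)
      refl <- reflectance_from_bi(bi)

      id <- trees$series_id[i]
      trw_rows[[i]] <- data.frame(series_id = id, year = years_i,
                                  value = round(trw, 3))
      refl_rows[[i]] <- data.frame(series_id = id, year = years_i,
                                   value = round(refl, 2))
    }
    trw_rd <- ring_data(do.call(rbind, trw_rows), proxy = "TRW",
                        trees = trees)
    refl_rd <- ring_data(do.call(rbind, refl_rows), proxy = "reflectance",
                         trees = trees)
    structure(list(trw = trw_rd, reflectance = refl_rd, trees = trees,
                   truth = list(signal_start = scenario$signal_start,
                                signal_width = scenario$signal_width,
                                beta = beta,
                                bi_signal_start = scenario$bi$signal_start,
                                bi_signal_width = scenario$bi$signal_width,
                                bi_beta = beta_bi,
                                seed = seed)),
              class = "ring_sim")
  })
}

#' @export
print.ring_sim <- function(x, ...) {
  cat("<ring_sim>\n  ")
  print(x$trw)
  cat("  true growth-signal window: ",
      window_label(x$truth$signal_start, x$truth$signal_width),
      sprintf(" (beta = %.4f)\n", x$truth$beta), sep = "")
  invisible(x)
}
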