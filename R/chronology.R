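#' Tukey biweight robust mean
#'
#' Robust location estimate used for chronology aggregation: starting at the
#' median, observations are weighted by `(1 - u^2)^2` with
#' `u = (x - loc) / (9 * MAD)` (weights zero for `|u| >= 1`) and the weighted
#' mean is iterated to convergence (tolerance 1e-8, at most 50 iterations).
#' With one or two values, or when the MAD is zero, the estimate reduces to
#' the arithmetic mean or median respectively.
#'
#' @param x numeric sample with at least one finite value; `NA`s are dropped.
#' @return the robust location, always within `[min(x), max(x)]`.
#' @examples
#' biweight_mean(c(1, 1, 1, 1, 10))  # outlier nearly ignored
#' @export
biweight_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("empty sample")
  if (length(x) <= 2L) return(mean(x))
  loc <- median(x)
  mad0 <- median(abs(x - loc))
  if (mad0 == 0) return(loc)
  for (i in seq_len(50L)) {
    u <- (x - loc) / (9 * mad0)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    new <- sum(w * x) / sum(w)
    if (abs(new - loc) < 1e-8) return(new)
    loc <- new
    mad0 <- median(abs(x - loc))
    if (mad0 == 0) return(loc)
  }
  loc
}

#' Build a master chronology from index series
#'
#' Averages the per-tree index series year by year with the Tukey biweight
#' robust mean (no variance stabilization), recording the number of series
#' contributing to each year (sample depth).
#'
#' @param x a `ring_indices` object from [detrend_dataset()], or a
#'   year-by-series numeric matrix with years as rownames.
#' @param type which index to aggregate when `x` is `ring_indices`:
#'   `"residual"` (prewhitened, the default) or `"standard"`.
#' @return object of class `chronology`: data frame with columns `year`,
#'   `index`, `depth`, plus attributes `proxy` and `type`.
#' @export
build_chronology <- function(x, type = c("residual", "standard")) {
  type <- match.arg(type)
  proxy <- NA_character_
  if (inherits(x, "ring_indices")) {
    proxy <- x$proxy
    x <- if (type == "residual") x$res else x$std
  }
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  if (ncol(x) < 2L) stop("need at least 2 series to build a chronology")
  depth <- rowSums(!is.na(x))
  if (!any(depth >= 2L))
    stop("series never overlap: cannot build a chronology")
  keep <- depth >= 1L
  idx <- apply(x[keep, , drop = FALSE], 1L, biweight_mean)
  out <- data.frame(year = as.integer(rownames(x))[keep],
                    index = unname(idx),
                    depth = unname(depth[keep]))
  structure(out, class = c("chronology", "data.frame"),
            proxy = proxy, type = type)
}

#' @export
print.chronology <- function(x, ...) {
  cat(sprintf("<chronology> %s (%s index): %d-%d, depth %d-%d\n",
              attr(x, "proxy"), attr(x, "type"),
              min(x$year), max(x$year), min(x$depth), max(x$depth)))
  invisible(x)
}

#' @export
plot.chronology <- function(x, ...) {
  graphics::plot(x$year, x$index, type = "l",
                 xlab = "year", ylab = "index", ...)
  graphics::abline(h = mean(x$index), lty = 3)
}

#' Mean sensitivity of a series
#'
#' Mean absolute relative year-to-year difference,
#' `mean(|2 * (x[t+1] - x[t]) / (x[t+1] + x[t])|)`: the classical measure of
#' interannual variability of a ring series. Scale-invariant.
#'
#' @param x non-negative numeric series, length >= 2; no adjacent pair may
#'   sum to zero.
#' @return the mean sensitivity, >= 0.
#' @export
mean_sensitivity <- function(x) {
  stopifnot(length(x) >= 2L, all(is.finite(x)), all(x >= 0))
  s <- x[-1L] + x[-length(x)]
  if (any(s == 0)) stop("adjacent values sum to zero: mean sensitivity undefined")
  mean(abs(2 * (x[-1L] - x[-length(x)]) / s))
}

#' Inter-series correlation and expressed population signal
#'
#' `rbar` is the mean of all pairwise Pearson correlations between series
#' over their pairwise overlap years; `EPS = n * rbar / (n * rbar + 1 - rbar)`
#' with `n` the mean sample depth over the analysis window. EPS above 0.85 is
#' the conventional threshold for a chronology to be considered a reliable
#' estimate of the population signal.
#'
#' @param x year-by-series matrix (e.g. the `res` element of `ring_indices`),
#'   or a `ring_indices` object (residual index used).
#' @param years optional calendar-year window to restrict the computation to.
#' @param min_overlap minimum pairwise overlap (years) for a pair to enter
#'   rbar; default 10.
#' @return list with `rbar`, `eps`, `n_bar` (mean sample depth) and `n_pairs`.
#' @export
rbar_eps <- function(x, years = NULL, min_overlap = 10) {
  if (inherits(x, "ring_indices")) x <- x$res
  stopifnot(is.matrix(x))
  if (!is.null(years)) {
    keep <- as.integer(rownames(x)) %in% years
    x <- x[keep, , drop = FALSE]
  }
  if (ncol(x) < 2L) stop("need at least 2 series")
  m <- ncol(x)
  cors <- c()
  for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
    ok <- !is.na(x[, i]) & !is.na(x[, j])
    if (sum(ok) >= min_overlap) {
      r <- suppressWarnings(cor(x[ok, i], x[ok, j]))
      if (is.finite(r)) cors <- c(cors, r)
    }
  }
  if (length(cors) == 0L)
    stop("no series pair overlaps by at least ", min_overlap, " years")
  rbar <- mean(cors)
  n_bar <- mean(rowSums(!is.na(x))[rowSums(!is.na(x)) > 0])
  list(rbar = rbar, eps = eps_from_rbar(n_bar, rbar),
       n_bar = n_bar, n_pairs = length(cors))
}

#' Expressed population signal from mean depth and rbar
#'
#' @param n_bar mean number of series per year.
#' @param rbar mean inter-series correlation.
#' @return `n_bar * rbar / (n_bar * rbar + 1 - rbar)`.
#' @export
eps_from_rbar <- function(n_bar, rbar) {
  stopifnot(n_bar > 0, rbar >= -1, rbar <= 1)
  (n_bar * rbar) / (n_bar * rbar + 1 - rbar)
}

#' Summary statistics of a ring dataset and its chronology
#'
#' Computes the classical chronology descriptors: mean series length
#' (mean/min/max, years), average growth rate (pooled mean of raw values,
#' with pooled SD, in proxy units), rbar and mean sensitivity of the residual
#' index series over the analysis window, mean first-order autocorrelation of
#' the raw series, and EPS.
#'
#' @param raw the raw `ring_data`.
#' @param indices matching `ring_indices` from [detrend_dataset()].
#' @param years optional analysis window (calendar years) for rbar/EPS/mean
#'   sensitivity; defaults to the full span.
#' @return one-row data frame with columns `proxy`, `n_series`,
#'   `length_mean`, `length_min`, `length_max`, `agr`, `agr_sd`, `rbar`,
#'   `mean_sens`, `auto_corr`, `eps`, `n_bar`.
#' @export
chronology_stats <- function(raw, indices, years = NULL) {
  stopifnot(inherits(raw, "ring_data"), inherits(indices, "ring_indices"))
  sl <- series_lengths(raw)
  vals <- as.vector(raw$wide)
  ac1 <- vapply(series_list(raw), function(s) {
    v <- s$values
    suppressWarnings(cor(v[-1L], v[-length(v)]))
  }, 0)
  resm <- indices$res
  if (!is.null(years)) {
    keep <- as.integer(rownames(resm)) %in% years
    resm <- resm[keep, , drop = FALSE]
  }
  ms <- vapply(seq_len(ncol(resm)), function(j) {
    v <- resm[!is.na(resm[, j]), j]
    if (length(v) >= 2L) mean_sensitivity(v) else NA_real_
  }, 0)
  re <- rbar_eps(resm)
  data.frame(proxy = raw$proxy,
             n_series = ncol(raw$wide),
             length_mean = mean(sl), length_min = min(sl),
             length_max = max(sl),
             agr = mean(vals, na.rm = TRUE),
             agr_sd = sd(vals, na.rm = TRUE),
             rbar = re$rbar,
             mean_sens = mean(ms, na.rm = TRUE),
             auto_corr = mean(ac1, na.rm = TRUE),
             eps = re$eps,
             n_bar = re$n_bar)
}

#' Segment crossdating check
#'
#' COFECHA-style dating verification: each series is spline-detrended,
#' cut into segments (default 50 years, 25-year overlap between consecutive
#' segments), and each segment is correlated against the leave-one-out master
#' (biweight mean of all other detrended series) over the same years.
#' Segments whose correlation falls below the one-tailed critical value at
#' p < 0.01 are flagged as possible dating errors. Flags are warnings for the
#' analyst, never automatic exclusions.
#'
#' @param x a `ring_data`.
#' @param seg_len segment length in years, default 50.
#' @param overlap overlap between consecutive segments, default 25.
#' @param wavelength spline wavelength used for the internal detrending.
#' @return data frame of class `crossdate` with one row per (series,
#'   segment): `series_id`, `start`, `end`, `n`, `r`, `r_crit`, `flag`.
#' @export
crossdating_check <- function(x, seg_len = 50, overlap = 25, wavelength = 30) {
  stopifnot(inherits(x, "ring_data"), seg_len > overlap)
  if (ncol(x$wide) < 2L) stop("need at least 2 series to crossdate")
  yrs <- series_years(x)
  std <- x$wide
  std[] <- NA_real_
  for (s in series_list(x)) {
    if (length(s$values) < 4L) next
    f <- spline_fit(s$values, wavelength = wavelength)
    rows <- as.character(seq.int(s$first_year, length.out = length(s$values)))
    std[rows, s$id] <- to_standard_index(s$values, f)
  }
  rows_out <- list()
  for (id in series_ids(x)) {
    v <- std[, id]
    ok <- which(!is.na(v))
    if (length(ok) == 0L) next
    if (length(ok) < seg_len)
      warning("series ", id, " shorter than segment length; single truncated segment")
    others <- std[, setdiff(series_ids(x), id), drop = FALSE]
    master <- apply(others, 1L, function(r) {
      r <- r[!is.na(r)]
      if (length(r)) biweight_mean(r) else NA_real_
    })
    starts <- seq.int(ok[1L], max(ok[1L], ok[length(ok)] - seg_len + 1L),
                      by = seg_len - overlap)
    for (st in starts) {
      en <- min(st + seg_len - 1L, ok[length(ok)])
      seg <- st:en
      use <- seg[!is.na(v[seg]) & !is.na(master[seg])]
      if (length(use) < 10L) next
      r <- suppressWarnings(cor(v[use], master[use]))
      rc <- critical_r(length(use), p = 0.01, tails = 1)
      rows_out[[length(rows_out) + 1L]] <-
        data.frame(series_id = id, start = yrs[st], end = yrs[en],
                   n = length(use), r = r, r_crit = rc,
                   flag = is.na(r) || r < rc)
    }
  }
  out <- do.call(rbind, rows_out)
  structure(out, class = c("crossdate", "data.frame"))
}

#' Restrict a chronology to the years covered by a climate record
#'
#' Mirrors the common-period truncation of dendroclimatic studies: only
#' calendar years whose daily record is (essentially) complete in the climate
#' series are retained.
#'
#' @param chron a `chronology`.
#' @param climate a `daily_climate`, or an integer vector of covered years.
#' @param min_frac minimum fraction of a year's days that must be present for
#'   the year to count as covered; default 0.95.
#' @return the truncated `chronology`.
#' @export
truncate_common_period <- function(chron, climate, min_frac = 0.95) {
  stopifnot(inherits(chron, "chronology"))
  yrs <- if (inherits(climate, "daily_climate"))
    climate_years(climate, min_frac = min_frac)
  else as.integer(climate)
  keep <- chron$year %in% yrs
  if (!any(keep)) stop("chronology and climate record do not overlap")
  out <- chron[keep, , drop = FALSE]
  structure(out, class = class(chron),
            proxy = attr(chron, "proxy"), type = attr(chron, "type"))
}

#' Critical Pearson correlation from the t distribution
#'
#' Inverts the t test for a correlation coefficient: the smallest `|r|`
#' significant at level `p` with `n` paired observations.
#'
#' @param n sample size (> 2).
#' @param p significance level, default 0.05.
#' @param tails 2 (default) or 1.
#' @return critical `|r|`.
#' @examples
#' critical_r(15)  # ~0.514
#' @export
critical_r <- function(n, p = 0.05, tails = 2) {
  stopifnot(n > 2, p > 0, p < 1, tails %in% c(1, 2))
  tq <- qt(1 - p / tails, df = n - 2)
  tq / sqrt(n - 2 + tq^2)
}
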