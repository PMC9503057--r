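# Season axis: day 1 = June 1 of the year before ring formation, day 518 =
# October 31 of the ring year. February 29 is dropped before gridding so the
# axis has the same length for every growth year.

SEASON_LEN <- 518L
PREV_LEN <- 214L  # Jun 1 .. Dec 31 of the previous year

# season dates for growth year y, Feb 29 removed
season_dates <- function(year) {
  d <- seq(as.Date(sprintf("%d-06-01", year - 1L)),
           as.Date(sprintf("%d-10-31", year)), by = "day")
  d[!(format(d, "%m-%d") == "02-29")]
}

#' Season-day index of a calendar date
#'
#' Maps (month, day) to the 1..518 index of the growth-year axis running from
#' previous-year June 1 to current-year October 31 (February 29 excluded).
#'
#' @param month,day calendar month (1-12) and day of month.
#' @param previous `TRUE` if the date falls in the year before ring
#'   formation (valid months 6-12), `FALSE` for the ring year (months 1-10).
#' @return integer season-day index.
#' @examples
#' season_index(12, 1, previous = TRUE)   # Dec 1, previous year -> 184
#' season_index(8, 15, previous = FALSE)  # Aug 15, current year -> 441
#' @export
season_index <- function(month, day, previous) {
  stopifnot(month %in% 1:12, day >= 1, day <= 31)
  days_in <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  if (day > days_in[month]) stop("invalid day of month")
  if (previous) {
    if (month < 6) stop("previous-year season days run June-December")
    offset <- c(0, cumsum(days_in))[month] - c(0, cumsum(days_in))[6L]
    offset + day
  } else {
    if (month > 10) stop("current-year season days run January-October")
    PREV_LEN + c(0, cumsum(days_in))[month] + day
  }
}

# inverse of season_index: list(month, day, previous)
season_date_parts <- function(idx) {
  stopifnot(idx >= 1, idx <= SEASON_LEN)
  days_in <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  if (idx <= PREV_LEN) {
    rem <- idx
    for (m in 6:12) {
      if (rem <= days_in[m]) return(list(month = m, day = rem, previous = TRUE))
      rem <- rem - days_in[m]
    }
  } else {
    rem <- idx - PREV_LEN
    for (m in 1:10) {
      if (rem <= days_in[m]) return(list(month = m, day = rem, previous = FALSE))
      rem <- rem - days_in[m]
    }
  }
  stop("season index out of range")  # unreachable
}

#' Human-readable label for a cumulative window
#'
#' Formats a (start day, width) window as a calendar span. Months in the
#' previous year are printed in lowercase, months in the ring year
#' capitalized (the convention of dendroclimatic correlation plots); windows
#' lying entirely in the previous year carry an explicit qualifier.
#'
#' @param start season-day index of the first day (see [season_index()]).
#' @param width window width in days, within `[min_width, max_width]`.
#' @param min_width,max_width allowed width range, defaults 21 and 120.
#' @return character label, e.g. `"dec 3 – Jan 18"`.
#' @export
window_label <- function(start, width, min_width = 21, max_width = 120) {
  stopifnot(length(start) == 1L, length(width) == 1L)
  if (width < min_width || width > max_width)
    stop("window width ", width, " outside [", min_width, ", ", max_width, "]")
  if (start < 1 || start + width - 1 > SEASON_LEN)
    stop("window extends outside the season axis")
  fmt <- function(parts) {
    m <- month.abb[parts$month]
    if (parts$previous) m <- tolower(m)
    paste(m, parts$day)
  }
  a <- season_date_parts(start)
  b <- season_date_parts(start + width - 1L)
  lab <- paste(fmt(a), "–", fmt(b))
  if (b$previous) lab <- paste0(lab, " (previous year)")
  lab
}

#' Cumulative daily temperature windows over the growth year
#'
#' For every growth year, lays the daily mean temperatures on the 518-day
#' season axis (previous June 1 to current October 31, February 29 dropped)
#' and computes the arithmetic mean of every cumulative window: each start
#' day 1..518 combined with each width (default 21..120 days), subject to the
#' window ending on or before current October 31. A window is computed when
#' at least `min_frac` of its days are present (mean over present days);
#' otherwise the cell is `NA`. A growth year with no data at all is an error.
#'
#' @param climate a `daily_climate` covering previous June 1 of the first
#'   growth year through October 31 of the last.
#' @param years integer vector of growth years.
#' @param widths window widths in days, default `21:120`.
#' @param min_frac minimum fraction of days present per window, default 0.95.
#' @return object of class `season_grid`: list with `years`, `cells` (data
#'   frame `start`, `width`, one row per window), `means` (matrix, years x
#'   cells) and `widths`.
#' @export
season_grid <- function(climate, years, widths = 21:120, min_frac = 0.95) {
  stopifnot(inherits(climate, "daily_climate"), length(years) >= 1L)
  widths <- sort(unique(as.integer(widths)))
  stopifnot(all(widths >= 1L), all(widths <= SEASON_LEN))
  cells <- do.call(rbind, lapply(widths, function(w)
    data.frame(start = seq_len(SEASON_LEN - w + 1L), width = w)))
  starts <- cells$start
  ends <- cells$start + cells$width - 1L
  need <- ceiling(min_frac * cells$width)

  temp <- climate$data$tmean
  names(temp) <- format(climate$data$date)
  means <- matrix(NA_real_, length(years), nrow(cells),
                  dimnames = list(years, NULL))
  for (k in seq_along(years)) {
    d <- season_dates(years[k])
    v <- unname(temp[format(d)])
    pres <- !is.na(v)
    if (!any(pres))
      stop("no climate data for growth year ", years[k])
    cs <- cumsum(ifelse(pres, v, 0))
    cn <- cumsum(pres)
    s0 <- c(0, cs)[starts]
    n0 <- c(0L, cn)[starts]
    wsum <- cs[ends] - s0
    wn <- cn[ends] - n0
    mu <- wsum / wn
    mu[wn < need] <- NA_real_
    means[k, ] <- mu
  }
  structure(list(years = as.integer(years), cells = cells, means = means,
                 widths = widths),
            class = "season_grid")
}

#' @export
print.season_grid <- function(x, ...) {
  cat(sprintf("<season_grid> %d growth years (%d-%d), %d windows (widths %d-%d d)\n",
              length(x$years), min(x$years), max(x$years), nrow(x$cells),
              min(x$widths), max(x$widths)))
  cat(sprintf("  %d cells missing\n", sum(is.na(x$means))))
  invisible(x)
}

#' Annual series of one fixed window's mean temperature
#'
#' @param grid a `season_grid`.
#' @param start,width the window.
#' @return data frame `year`, `temp`.
#' @export
window_series <- function(grid, start, width) {
  stopifnot(inherits(grid, "season_grid"))
  j <- which(grid$cells$start == start & grid$cells$width == width)
  if (length(j) != 1L) stop("window not present in grid")
  data.frame(year = grid$years, temp = grid$means[, j])
}
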