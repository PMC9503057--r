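#' Read a Tucson/RWL ring-width file
#'
#' Parses the decadal Tucson format used by the ITRDB. Each data line carries
#' a series id, the calendar year of its first value, and up to ten annual
#' values; a series ends with a sentinel value. The measurement unit is
#' detected per series from that sentinel: `-9999` means values are stored in
#' 0.001 mm, `999` means 0.01 mm. Values are returned in mm.
#'
#' @param path path to an RWL file.
#' @param trees optional tree-metadata data frame passed to [ring_data()].
#' @return a [ring_data()] object with `proxy = "TRW"`.
#' @seealso [write_rwl()]
#' @export
read_rwl <- function(path, trees = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("empty RWL file: ", path)

  acc <- list()   # per-series accumulator: first_year, raw integer values
  order_seen <- character(0)
  closed <- character(0)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(tok) < 3L)
      stop("malformed RWL line ", lineno[i], ": expected id, year, values")
    id <- tok[1L]
    yr <- suppressWarnings(as.integer(tok[2L]))
    vals <- suppressWarnings(as.integer(tok[-(1:2)]))
    if (is.na(yr))
      stop("malformed RWL line ", lineno[i], ": unreadable decade year")
    if (anyNA(vals))
      stop("malformed RWL line ", lineno[i], ": unreadable measurement")
    if (id %in% closed)
      stop("duplicate series id in RWL file: ", id)
    if (is.null(acc[[id]])) {
      acc[[id]] <- list(first_year = yr, values = integer(0), next_year = yr)
      order_seen <- c(order_seen, id)
    } else if (yr != acc[[id]]$next_year) {
      stop("malformed RWL line ", lineno[i], ": decade year ", yr,
           " does not continue series ", id, " (expected ",
           acc[[id]]$next_year, ")")
    }
    sentinel <- match(TRUE, vals %in% c(999L, -9999L))
    if (!is.na(sentinel)) {
      body <- vals[seq_len(sentinel - 1L)]
      acc[[id]]$values <- c(acc[[id]]$values, body)
      acc[[id]]$unit <- if (vals[sentinel] == -9999L) 0.001 else 0.01
      closed <- c(closed, id)
    } else {
      acc[[id]]$values <- c(acc[[id]]$values, vals)
      acc[[id]]$next_year <- yr + length(vals)
    }
  }
  open <- setdiff(order_seen, closed)
  if (length(open))
    stop("series without terminating sentinel (999/-9999): ",
         paste(open, collapse = ", "))
  sl <- lapply(order_seen, function(id) {
    a <- acc[[id]]
    if (length(a$values) == 0L) stop("series ", id, " has no values")
    list(id = id, first_year = a$first_year, values = a$values * a$unit)
  })
  from_series_list(sl, proxy = "TRW", trees = trees)
}

#' Write a ring-width dataset as a Tucson/RWL file
#'
#' Exports in 0.001 mm units with the `-9999` end-of-series sentinel. Only
#' ring-width datasets can be represented at RWL integer precision; BI or BAI
#' data must go through [write_series_csv()].
#'
#' @param x a `ring_data` with `proxy = "TRW"`; series ids at most 8
#'   characters.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(x, path) {
  stopifnot(inherits(x, "ring_data"))
  if (x$proxy != "TRW")
    stop(x$proxy, " data cannot be written as RWL; use write_series_csv()")
  if (ncol(x$wide) == 0L) stop("empty dataset")
  ids <- series_ids(x)
  if (any(nchar(ids) > 8L))
    stop("series ids longer than 8 characters: ",
         paste(ids[nchar(ids) > 8L], collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  for (s in series_list(x)) {
    ints <- as.integer(round(s$values * 1000))
    years <- seq.int(s$first_year, length.out = length(ints))
    codes <- c(ints, -9999L)
    years <- c(years, years[length(years)] + 1L)
    i <- 1L
    while (i <= length(codes)) {
      decade_end <- (years[i] %/% 10L) * 10L + 9L
      j <- min(which(years > decade_end) - 1L, length(codes))
      if (!length(j) || j < i) j <- length(codes)
      writeLines(sprintf("%-8s%6d%s", s$id, years[i],
                         paste(sprintf("%6d", codes[i:j]), collapse = "")),
                 con)
      i <- j + 1L
    }
  }
  invisible(path)
}

#' Read or write long-format series CSV
#'
#' Long CSV (`series_id,year,value`) is the interchange format for BI, BAI
#' and any other series that RWL integer precision cannot hold.
#'
#' @param path CSV path.
#' @param proxy proxy kind of the stored values (see [ring_data()]).
#' @param trees optional tree table forwarded to [ring_data()].
#' @return `read_series_csv()` returns a `ring_data`; `write_series_csv()`
#'   returns `path` invisibly.
#' @export
read_series_csv <- function(path, proxy, trees = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ring_data(df, proxy = proxy, trees = trees)
}

#' @rdname read_series_csv
#' @param x a `ring_data` object.
#' @export
write_series_csv <- function(x, path) {
  stopifnot(inherits(x, "ring_data"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a tree metadata table
#'
#' @param path CSV with columns `series_id`, `dbh_mm` and optionally
#'   `elevation`.
#' @return data frame suitable for the `trees` argument of [ring_data()].
#' @export
read_tree_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_trees(df, df$series_id)
}

#' Read a daily mean-temperature series
#'
#' @param path delimited file with a date column (ISO-8601) and a temperature
#'   column (degrees Celsius).
#' @param date_col,temp_col column names; defaults `"date"` and `"tmean"`.
#' @param station_id optional label carried through to reports.
#' @return object of class `daily_climate`: list with `station_id`, `data`
#'   (data frame `date`, `tmean`, one row per present day, strictly
#'   increasing) and `gaps` (Date vector of missing days inside the record
#'   span).
#' @export
read_daily_climate <- function(path, date_col = "date", temp_col = "tmean",
                               station_id = basename(path)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c(date_col, temp_col) %in% names(df)))
    stop("climate file must have columns '", date_col, "' and '", temp_col, "'")
  dates <- as.Date(as.character(df[[date_col]]), format = "%Y-%m-%d")
  if (anyNA(dates))
    stop("unparseable date at row ", which(is.na(dates))[1L])
  tv <- df[[temp_col]]
  tnum <- suppressWarnings(as.numeric(tv))
  if (anyNA(tnum))
    stop("non-numeric temperature at row ", which(is.na(tnum))[1L])
  if (any(!is.finite(tnum)))
    stop("non-finite temperature at row ", which(!is.finite(tnum))[1L])
  if (any(diff(as.integer(dates)) <= 0))
    stop("dates must be strictly increasing (row ",
         which(diff(as.integer(dates)) <= 0)[1L] + 1L, ")")
  daily_climate(dates, tnum, station_id = station_id)
}

# internal constructor shared with the simulator
daily_climate <- function(dates, tmean, station_id = "station") {
  full <- seq(min(dates), max(dates), by = "day")
  gaps <- full[!(full %in% dates)]
  structure(list(station_id = station_id,
                 data = data.frame(date = dates, tmean = tmean),
                 gaps = gaps),
            class = "daily_climate")
}

#' @export
print.daily_climate <- function(x, ...) {
  cat(sprintf("<daily_climate> %s: %d records, %s to %s (%d gap days)\n",
              x$station_id, nrow(x$data), min(x$data$date), max(x$data$date),
              length(x$gaps)))
  invisible(x)
}

#' Write a daily climate series as CSV
#' @param x a `daily_climate` object.
#' @param path output CSV path.
#' @export
write_daily_climate <- function(x, path) {
  stopifnot(inherits(x, "daily_climate"))
  write.csv(data.frame(date = format(x$data$date), tmean = x$data$tmean),
            path, row.names = FALSE)
  invisible(path)
}

# calendar years whose days are (at least min_frac) present in the record
climate_years <- function(climate, min_frac = 0.95) {
  yr <- as.integer(format(climate$data$date, "%Y"))
  cnt <- table(yr)
  full <- ifelse(as.integer(names(cnt)) %% 4L == 0L &
                   (as.integer(names(cnt)) %% 100L != 0L |
                      as.integer(names(cnt)) %% 400L == 0L), 366L, 365L)
  as.integer(names(cnt))[as.integer(cnt) >= ceiling(min_frac * full)]
}
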