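#' Assemble a ring dataset from long-format measurements
#'
#' A `ring_data` object holds one site's collection of annual tree-ring
#' series of a single proxy kind, aligned on calendar years, plus (optionally)
#' the per-tree metadata needed for basal-area reconstruction. Internally the
#' series live in a year-by-series matrix padded with `NA` outside each
#' series' span, the layout the chronology and statistics code operates on.
#'
#' @param df data frame with columns `series_id`, `year`, `value`; one row per
#'   measured ring. Years within a series must be consecutive (tree rings have
#'   no gaps).
#' @param proxy proxy kind: `"TRW"` (ring width, mm), `"BAI"` (basal area
#'   increment, mm^2), `"BI"` (adjusted blue intensity, unitless) or
#'   `"reflectance"` (raw blue reflectance, 0--255).
#' @param trees optional data frame of tree metadata with columns `series_id`,
#'   `dbh_mm` (mean breast-height diameter at coring, mm) and optionally
#'   `elevation` (site class, e.g. `"low"`/`"high"`).
#' @return an object of class `ring_data`: list with elements `wide`
#'   (year x series numeric matrix, rownames = years), `proxy`, `trees`.
#' @examples
#' df <- data.frame(series_id = "T01", year = 2000:2004, value = c(1.2, 1.1, 0.9, 1.4, 1.0))
#' rd <- ring_data(df, proxy = "TRW")
#' summary(rd)
#' @export
ring_data <- function(df, proxy = c("TRW", "BAI", "BI", "reflectance"),
                      trees = NULL) {
  proxy <- match.arg(proxy)
  need <- c("series_id", "year", "value")
  if (!all(need %in% names(df)))
    stop("`df` must have columns series_id, year, value")
  if (nrow(df) == 0L) stop("empty ring dataset")
  df$series_id <- as.character(df$series_id)
  df$year <- as.integer(df$year)
  ids <- unique(df$series_id)
  years <- seq.int(min(df$year), max(df$year))
  wide <- matrix(NA_real_, length(years), length(ids),
                 dimnames = list(years, ids))
  for (id in ids) {
    sub <- df[df$series_id == id, , drop = FALSE]
    sub <- sub[order(sub$year), , drop = FALSE]
    if (anyDuplicated(sub$year))
      stop("duplicate year in series ", id)
    if (!all(diff(sub$year) == 1L))
      stop("gap in series ", id, ": ring years must be consecutive")
    check_proxy_values(sub$value, proxy, id)
    wide[as.character(sub$year), id] <- sub$value
  }
  trees <- validate_trees(trees, ids)
  structure(list(wide = wide, proxy = proxy, trees = trees),
            class = "ring_data")
}

check_proxy_values <- function(v, proxy, id) {
  if (anyNA(v) || !all(is.finite(v)))
    stop("non-finite value in series ", id)
  if (proxy == "TRW" && any(v < 0))
    stop("negative ring width in series ", id)
  if (proxy == "BI" && (any(v <= 0) || any(v > 2.56)))
    stop("BI values must lie in (0, 2.56]: series ", id)
  if (proxy == "reflectance" && (any(v < 0) || any(v > 255)))
    stop("reflectance values must lie in [0, 255]: series ", id)
  if (proxy == "BAI" && any(v < 0))
    stop("negative basal area increment in series ", id)
  invisible(v)
}

validate_trees <- function(trees, ids) {
  if (is.null(trees)) return(NULL)
  if (!all(c("series_id", "dbh_mm") %in% names(trees)))
    stop("`trees` must have columns series_id, dbh_mm")
  trees$series_id <- as.character(trees$series_id)
  if (anyDuplicated(trees$series_id))
    stop("duplicate series_id in tree table")
  if (any(!is.finite(trees$dbh_mm)) || any(trees$dbh_mm <= 0))
    stop("dbh_mm must be positive and finite")
  if (is.null(trees$elevation)) trees$elevation <- "all"
  trees[, c("series_id", "dbh_mm", "elevation")]
}

#' @export
print.ring_data <- function(x, ...) {
  yrs <- as.integer(rownames(x$wide))
  cat(sprintf("<ring_data> %s: %d series, %d-%d\n",
              x$proxy, ncol(x$wide), min(yrs), max(yrs)))
  if (!is.null(x$trees))
    cat(sprintf("  tree metadata for %d series (%s)\n", nrow(x$trees),
                paste(unique(x$trees$elevation), collapse = ", ")))
  invisible(x)
}

#' @export
summary.ring_data <- function(object, ...) {
  sl <- series_lengths(object)
  cat(sprintf("<ring_data> %s proxy, %d series\n", object$proxy, ncol(object$wide)))
  cat(sprintf("  series length: mean %.1f, range %d-%d yr\n",
              mean(sl), min(sl), max(sl)))
  cat(sprintf("  value mean %.4g, sd %.4g\n",
              mean(object$wide, na.rm = TRUE), sd(as.vector(object$wide), na.rm = TRUE)))
  invisible(object)
}

#' @export
as.data.frame.ring_data <- function(x, ...) {
  yrs <- as.integer(rownames(x$wide))
  out <- do.call(rbind, lapply(colnames(x$wide), function(id) {
    ok <- !is.na(x$wide[, id])
    data.frame(series_id = id, year = yrs[ok], value = x$wide[ok, id])
  }))
  rownames(out) <- NULL
  out
}

# ---- small accessors used throughout ----------------------------------------

series_ids <- function(x) colnames(x$wide)

series_years <- function(x) as.integer(rownames(x$wide))

series_lengths <- function(x) colSums(!is.na(x$wide))

# list of (id, first_year, values) per series
series_list <- function(x) {
  yrs <- series_years(x)
  lapply(series_ids(x), function(id) {
    v <- x$wide[, id]
    ok <- which(!is.na(v))
    list(id = id, first_year = yrs[ok[1L]], values = unname(v[ok]))
  })
}

# rebuild a ring_data from a series_list-shaped list
from_series_list <- function(sl, proxy, trees = NULL) {
  df <- do.call(rbind, lapply(sl, function(s)
    data.frame(series_id = s$id,
               year = seq.int(s$first_year, length.out = length(s$values)),
               value = s$values)))
  ring_data(df, proxy = proxy, trees = trees)
}

#' Combine ring datasets of the same proxy kind
#'
#' Merges the series (and tree tables) of two or more `ring_data` objects,
#' e.g. to pool low- and high-elevation simulated stands.
#'
#' @param ... `ring_data` objects sharing a proxy kind; series ids must be
#'   unique across objects.
#' @return a single `ring_data`.
#' @export
combine_ring_data <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L)
  proxy <- unique(vapply(xs, function(x) x$proxy, ""))
  if (length(proxy) != 1L) stop("all datasets must share a proxy kind")
  df <- do.call(rbind, lapply(xs, as.data.frame))
  trees <- do.call(rbind, lapply(xs, function(x) x$trees))
  ring_data(df, proxy = proxy, trees = trees)
}
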