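#' Blue reflectance to blue intensity transform
#'
#' Converts raw latewood blue reflectance (8-bit scale, 0--255) into the
#' adjusted blue intensity proxy, `2.56 - x / 100`. The constant 2.56 keeps
#' every adjusted value positive, so BI can be ratio-detrended like a growth
#' series; the transform inverts the reflectance axis, making BI behave like
#' a density proxy (denser latewood reflects less blue light).
#'
#' @param x numeric vector of raw reflectance values in `[0, 255]`.
#' @return adjusted BI values in `(0, 2.56]`.
#' @examples
#' blue_intensity_transform(c(0, 100, 255))
#' @export
blue_intensity_transform <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("reflectance must be finite numeric")
  if (any(x < 0) || any(x > 255))
    stop("reflectance outside [0, 255]")
  2.56 - x / 100
}

# inverse, used by the synthetic generator so that analysis-side
# blue_intensity_transform() recovers the generated BI exactly
reflectance_from_bi <- function(bi) {
  stopifnot(all(bi > 0), all(bi <= 2.56))
  (2.56 - bi) * 100
}

#' Convert a raw reflectance dataset to adjusted BI
#'
#' @param x a `ring_data` with `proxy = "reflectance"`.
#' @return a `ring_data` with `proxy = "BI"`.
#' @export
build_bi <- function(x) {
  stopifnot(inherits(x, "ring_data"))
  if (x$proxy != "reflectance")
    stop("build_bi() expects raw reflectance data")
  df <- as.data.frame(x)
  df$value <- blue_intensity_transform(df$value)
  ring_data(df, proxy = "BI", trees = x$trees)
}

#' Reconstruct annual breast-height diameters from ring widths
#'
#' Walks backwards from the diameter measured in the coring year, removing
#' twice the radial increment of each ring:
#' `DBH(t-1) = DBH(t) - 2 * TRW(t)`. The factor 2 assumes radial symmetry of
#' growth around the stem. The returned vector has one more element than
#' `trw`: position 1 is the diameter inside the innermost measured ring, and
#' position `i + 1` the diameter at the end of ring year `i`; the last element
#' equals `dbh_final`.
#'
#' @param dbh_final measured diameter at breast height in the coring year, mm
#'   (mean of two perpendicular caliper readings, over bark).
#' @param trw ring widths in mm, ordered oldest to newest.
#' @param series_id optional label used in error messages.
#' @return numeric vector of length `length(trw) + 1`, strictly positive and
#'   non-decreasing.
#' @export
reconstruct_dbh <- function(dbh_final, trw, series_id = "series") {
  stopifnot(is.numeric(dbh_final), length(dbh_final) == 1L, dbh_final > 0,
            is.numeric(trw), length(trw) >= 1L, all(is.finite(trw)),
            all(trw >= 0))
  # cumulative removal from the outside in
  dbh <- dbh_final - 2 * rev(c(0, cumsum(rev(trw))))
  if (any(dbh <= 0))
    stop("reconstructed DBH non-positive for ", series_id,
         ": core growth is inconsistent with the measured DBH")
  dbh
}

#' Basal area increment between two diameters
#'
#' `BAI = pi/4 * (DBH_t^2 - DBH_{t-1}^2)`, the annual increment of stem
#' cross-sectional area at breast height.
#'
#' @param dbh_now,dbh_prev diameters in mm at the end and start of the ring
#'   year; both positive, `dbh_now >= dbh_prev`. Vectorized.
#' @return increment in mm^2.
#' @export
basal_area_increment <- function(dbh_now, dbh_prev) {
  stopifnot(length(dbh_now) == length(dbh_prev))
  if (any(dbh_prev <= 0)) stop("diameters must be positive")
  if (any(dbh_now < dbh_prev)) stop("dbh_now must be >= dbh_prev")
  (pi / 4) * (dbh_now^2 - dbh_prev^2)
}

#' Build a basal area increment dataset from ring widths and tree diameters
#'
#' For every series, the annual diameter sequence is reconstructed from the
#' coring-year DBH ([reconstruct_dbh()]) and converted ring by ring into
#' basal area increments ([basal_area_increment()]). The BAI series spans
#' exactly the years of its ring-width series.
#'
#' @param x a `ring_data` with `proxy = "TRW"` whose `trees` table provides a
#'   `dbh_mm` for every series (or pass `trees` explicitly).
#' @param trees optional tree table overriding `x$trees`.
#' @return a `ring_data` with `proxy = "BAI"`, carrying the same tree table.
#' @export
build_bai <- function(x, trees = NULL) {
  stopifnot(inherits(x, "ring_data"))
  if (x$proxy != "TRW") stop("build_bai() expects ring-width data")
  trees <- if (is.null(trees)) x$trees else validate_trees(trees, series_ids(x))
  if (is.null(trees)) stop("no tree table: BAI needs a DBH per series")
  missing <- setdiff(series_ids(x), trees$series_id)
  if (length(missing))
    stop("no DBH record for series: ", paste(missing, collapse = ", "))
  sl <- lapply(series_list(x), function(s) {
    dbh_final <- trees$dbh_mm[match(s$id, trees$series_id)]
    dbh <- reconstruct_dbh(dbh_final, s$values, series_id = s$id)
    n <- length(s$values)
    s$values <- basal_area_increment(dbh[-1L], dbh[-(n + 1L)])
    s
  })
  from_series_list(sl, proxy = "BAI", trees = trees)
}
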