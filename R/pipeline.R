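# End-to-end orchestration: proxies -> detrend -> chronology -> statistics ->
# window correlation -> moving stability, per proxy and elevation group, with
# CSV outputs and a run manifest.

#' Growth years fully covered by a climate record
#'
#' A growth year needs its whole season axis (previous June 1 to current
#' October 31); a year qualifies when at least `min_frac` of those 518 days
#' are present.
#'
#' @param climate a `daily_climate`.
#' @param min_frac minimum coverage fraction, default 0.95.
#' @return integer vector of usable growth years.
#' @export
growth_years <- function(climate, min_frac = 0.95) {
  present <- format(climate$data$date)
  span <- as.integer(format(range(climate$data$date), "%Y"))
  cand <- seq.int(span[1L], span[2L] + 1L)
  cand[vapply(cand, function(y) {
    d <- format(season_dates(y))
    mean(d %in% present) >= min_frac
  }, TRUE)]
}

#' Assemble and validate a pipeline run configuration
#'
#' Inputs may be given as file paths (RWL/CSV, read on run) or as in-memory
#' objects. Validation happens up front: requesting BAI without a tree table
#' or BI without reflectance data fails here, before any computation.
#'
#' @param trw ring-width input: path to an RWL file or a `ring_data` (TRW).
#' @param climate daily temperature input: CSV path or `daily_climate`.
#' @param trees tree metadata: CSV path, data frame, or `NULL` (then taken
#'   from `trw` if present). Required for BAI; its `elevation` column defines
#'   the site groups.
#' @param reflectance raw blue reflectance: long CSV path or `ring_data`
#'   (`proxy = "reflectance"`). Required for BI.
#' @param proxies which proxies to run, subset of `c("TRW", "BAI", "BI")`.
#' @param widths cumulative window widths in days, default `21:120`.
#' @param n_boot bootstrap replicates per grid cell, default 1000.
#' @param seed master seed; all randomness in the run flows from it.
#' @param out_dir output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @param wavelength,response spline detrending calibration.
#' @param ar_max_order maximum AR order for prewhitening.
#' @param stability_length moving-correlation block length in years.
#' @param plots also write heat-map / stability PNGs, default `FALSE`.
#' @return list of class `run_config`.
#' @export
run_config <- function(trw, climate, trees = NULL, reflectance = NULL,
                       proxies = c("TRW", "BAI", "BI"), widths = 21:120,
                       n_boot = 1000, seed = 1, out_dir = NULL,
                       wavelength = 30, response = 0.5, ar_max_order = 10,
                       stability_length = 15, plots = FALSE) {
  proxies <- match.arg(proxies, several.ok = TRUE)
  for (nm in c("trw", "climate", "trees", "reflectance")) {
    v <- get(nm)
    if (is.character(v) && !file.exists(v))
      stop("input file for '", nm, "' does not exist: ", v)
  }
  if ("BI" %in% proxies && is.null(reflectance))
    stop("proxy BI requested but no reflectance input given")
  cfg <- list(trw = trw, climate = climate, trees = trees,
              reflectance = reflectance, proxies = proxies,
              widths = widths, n_boot = n_boot, seed = seed,
              out_dir = out_dir, wavelength = wavelength,
              response = response, ar_max_order = ar_max_order,
              stability_length = stability_length, plots = plots)
  class(cfg) <- "run_config"
  cfg
}

load_input <- function(v, reader) if (is.character(v)) reader(v) else v

subset_series <- function(x, ids) {
  df <- as.data.frame(x)
  df <- df[df$series_id %in% ids, , drop = FALSE]
  trees <- x$trees
  if (!is.null(trees)) trees <- trees[trees$series_id %in% ids, , drop = FALSE]
  ring_data(df, proxy = x$proxy, trees = trees)
}

#' Run the full dendroclimatic pipeline
#'
#' For every elevation group in the tree table and every requested proxy:
#' derive the proxy series, detrend and prewhiten, build the residual
#' biweight chronology, compute chronology statistics, truncate to the
#' climate-covered growth years, correlate against every cumulative daily
#' temperature window with bootstrap significance, and assess the 15-year
#' moving stability of the best window. Results are returned and, when
#' `out_dir` is set, written as CSV (chronologies, statistics table, grid,
#' best windows, stability) plus a `manifest.json` recording the
#' configuration hash, seed and package version. The run is a pure function
#' of (inputs, configuration, seed).
#'
#' @param config a [run_config()].
#' @return invisibly, a nested list `results[[group]][[proxy]]` with elements
#'   `chronology`, `stats`, `grid_cor` ([correlate_grid()] result) and
#'   `stability` (or `NULL`), plus `$manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  trw <- load_input(config$trw, read_rwl)
  climate <- load_input(config$climate, read_daily_climate)
  trees <- load_input(config$trees, read_tree_table)
  if (is.null(trees)) trees <- trw$trees
  refl <- if (!is.null(config$reflectance))
    load_input(config$reflectance,
               function(p) read_series_csv(p, proxy = "reflectance"))
  if ("BAI" %in% config$proxies && is.null(trees))
    stop("proxy BAI requested but no tree table (DBH) available")
  if (!is.null(trees)) trw$trees <- validate_trees(trees, series_ids(trw))

  groups <- if (is.null(trees)) "all" else unique(trees$elevation)
  gyears <- growth_years(climate)
  out <- list()
  for (g in groups) {
    ids <- if (is.null(trees)) series_ids(trw)
    else trees$series_id[trees$elevation == g]
    out[[g]] <- list()
    for (px in config$proxies) {
      raw <- switch(px,
        TRW = subset_series(trw, ids),
        BAI = build_bai(subset_series(trw, ids)),
        BI  = build_bi(subset_series(refl, ids)))
      ind <- detrend_dataset(raw, wavelength = config$wavelength,
                             response = config$response,
                             ar_max_order = config$ar_max_order)
      crn <- build_chronology(ind, type = "residual")
      crn_t <- truncate_common_period(crn, intersect(crn$year, gyears))
      stats <- chronology_stats(raw, ind, years = crn_t$year)
      grid <- season_grid(climate, years = crn_t$year,
                          widths = config$widths)
      wc <- correlate_grid(crn_t, grid, n_boot = config$n_boot,
                           seed = config$seed)
      stab <- NULL
      if (!is.null(wc$best) &&
          nrow(crn_t) > config$stability_length) {
        ws <- window_series(grid, wc$best$start, wc$best$width)
        if (!anyNA(ws$temp))
          stab <- moving_stability(crn_t, ws,
                                   length = config$stability_length)
      }
      out[[g]][[px]] <- list(chronology = crn_t, stats = stats,
                             grid_cor = wc, stability = stab)
    }
  }
  out$manifest <- build_manifest(config)
  if (!is.null(config$out_dir)) write_run_outputs(out, config)
  invisible(out)
}

build_manifest <- function(config) {
  desc <- config[c("proxies", "n_boot", "seed", "wavelength", "response",
                   "ar_max_order", "stability_length")]
  desc$widths <- range(config$widths)
  desc$inputs <- lapply(config[c("trw", "climate", "trees", "reflectance")],
                        function(v) {
                          if (is.null(v)) NULL
                          else if (is.character(v)) v
                          else paste0("<in-memory ", class(v)[1L], ">")
                        })
  json <- jsonlite::toJSON(desc, auto_unbox = TRUE)
  list(config = desc, config_hash = fnv1a32(as.character(json)),
       seed = config$seed,
       package_version = as.character(packageVersion("ringclim")))
}

write_run_outputs <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stats_all <- list()
  best_all <- list()
  for (g in setdiff(names(out), "manifest")) {
    for (px in names(out[[g]])) {
      r <- out[[g]][[px]]
      stem <- file.path(config$out_dir, sprintf("%s_%s", px, g))
      write.csv(as.data.frame(r$chronology),
                paste0(stem, "_chronology.csv"), row.names = FALSE)
      write.csv(r$grid_cor$results, paste0(stem, "_grid.csv"),
                row.names = FALSE)
      if (!is.null(r$stability))
        write.csv(as.data.frame(r$stability), paste0(stem, "_stability.csv"),
                  row.names = FALSE)
      s <- r$stats
      s$group <- g
      stats_all[[paste(g, px)]] <- s
      if (!is.null(r$grid_cor$best)) {
        b <- r$grid_cor$best
        b$group <- g
        b$proxy <- px
        b$n_years <- r$grid_cor$n_years
        best_all[[paste(g, px)]] <- b
      }
      if (isTRUE(config$plots)) {
        grDevices::png(paste0(stem, "_grid.png"), 900, 600)
        plot(r$grid_cor, significant_only = FALSE,
             main = sprintf("%s %s", px, g))
        grDevices::dev.off()
        if (!is.null(r$stability)) {
          grDevices::png(paste0(stem, "_stability.png"), 900, 450)
          plot(r$stability, main = sprintf("%s %s", px, g))
          grDevices::dev.off()
        }
      }
    }
  }
  write.csv(do.call(rbind, stats_all),
            file.path(config$out_dir, "chronology_stats.csv"),
            row.names = FALSE)
  if (length(best_all))
    write.csv(do.call(rbind, best_all),
              file.path(config$out_dir, "best_windows.csv"),
              row.names = FALSE)
  jsonlite::write_json(out$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
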