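# ringclim

Dendroclimatic analysis of tree-ring proxies against **daily** temperature
data. `ringclim` builds residual chronologies from three ring proxies —
ring width (TRW, mm), basal area increment (BAI, mm²) and latewood blue
intensity (BI, unitless) — and correlates them with the mean temperature of
*every* cumulative daily window of 21–120 days across the growth year
(previous-year June 1 to current-year October 31), with bootstrap
significance and moving-window stability. It is aimed at dendrochronologists
who want the classical dplR-style standardization chain and a
dendroTools-style daily correlation engine in one tested, scriptable
pipeline, plus a synthetic-data generator with known ground truth for
validating every stage.

## The method

Per tree, raw measurements are standardized the classical way:

* **BI transform**: raw latewood blue reflectance `x ∈ [0, 255]` becomes
  `BI = 2.56 − x/100`, a positive density-like proxy.
* **BAI reconstruction**: diameters are walked back from the coring-year
  DBH, `DBH(t−1) = DBH(t) − 2·TRW(t)`, and ring area is
  `BAI(t) = (π/4)·(DBH(t)² − DBH(t−1)²)`.
* **Detrending**: a cubic-type smoothing spline with a 50% frequency cutoff
  at 30 years (TRW, BAI) or a Hugershoff curve `a·t^b·e^(−ct) + d` (BI);
  indices are the ratio raw/fitted.
* **Prewhitening**: AR(p) by AIC (Burg), keeping innovations re-centred on
  the index mean.
* **Chronology**: Tukey biweight robust mean across trees, no variance
  stabilization, with sample depth; quality described by Rbar (mean
  inter-series correlation), `EPS = n̄·Rbar / (n̄·Rbar + 1 − Rbar)`, mean
  sensitivity `mean |2(xₜ₊₁ − xₜ)/(xₜ₊₁ + xₜ)|`, raw lag-1 autocorrelation,
  and COFECHA-style 50-year/25-year-overlap crossdating checks.

The climate side lays daily mean temperatures on a fixed 518-day season
axis (Feb 29 dropped) and computes the mean of all ~45,000 cumulative
windows. Each window is correlated with the chronology by Pearson's r with
a bootstrap confidence interval (1000 pair resamples, BCa by default;
percentile optional); a window is significant when the 95% interval
excludes zero. The best significant window (max |r|) is reported with a
calendar label, and its 15-year step-1 moving correlation tracks signal
stability (parametric critical |r| ≈ 0.514 at n = 15, p < 0.05).

## Worked example

Simulate a 50-tree stand whose growth index carries a known winter
temperature signal, then run the analysis chain:

```r
library(ringclim)

scen    <- synthetic_scenario(seed = 42)   # 50 trees, 1978-2019, winter signal
climate <- simulate_daily_temperature(scen)
stand   <- simulate_ring_dataset(scen, climate)

idx <- detrend_dataset(stand$trw)          # spline + AR prewhitening
crn <- build_chronology(idx, type = "residual")
crn <- truncate_common_period(crn, growth_years(climate))
chronology_stats(stand$trw, idx, years = crn$year)

grid <- season_grid(climate, years = crn$year)   # 21-120 day windows
wc   <- correlate_grid(crn, grid, n_boot = 1000, seed = 1)
wc
stab <- moving_stability(crn, window_series(grid, wc$best$start, wc$best$width))
```

which prints:

```
  proxy n_series length_mean length_min length_max  agr agr_sd  rbar mean_sens
1   TRW       50        94.7         69        135 1.98  0.597 0.245      0.14
  auto_corr   eps n_bar
1     0.821 0.942    50

<window_cor_grid> 44850 windows, n = 42 years, 1000 bootstrap reps
  significant cells: 7577 (16.9%)
  best window: nov 29 – Jan 7 (start 182, width 40 d), r = 0.600

<moving_cor> 28 windows of 15 yr, critical |r| = 0.514, 26 significant
```

Reading this: the stand statistics sit where field chronologies of Norway
spruce do (mean growth ~2 mm/yr, Rbar ≈ 0.25, EPS ≈ 0.94 well above the
0.85 reliability threshold, strong raw temporal memory 0.82). The injected
signal was the 60-day window starting December 1 (previous year); the grid
search lands on a heavily overlapping late-November–January window at
r = 0.60, and that correlation is significant in 26 of the 28 fifteen-year
sub-periods. Lowercase months label the year before ring formation.

`run_pipeline(run_config(...))` chains all of the above per proxy and
elevation group and writes chronology/statistics/grid/stability CSVs plus a
run manifest; see `?run_pipeline`.

## Limitations

DBH is used over bark as measured; cores that miss the pith keep whatever
innermost diameter the recursion yields. The ~45k-cell correlation surface
carries no multiple-testing correction (none is standard in this setting);
neighbouring windows are strongly dependent, so the surface should be read
as a ridge, not as independent tests — the identified best window is
accordingly uncertain along that ridge. See the methods vignette
(`vignettes/daily-window-dendroclimatology.Rmd`) for the full account.
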