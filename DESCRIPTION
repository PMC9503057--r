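Package: ringclim
Title: Tree-Ring Chronologies and Daily Cumulative-Window Climate Correlation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds tree-ring width (TRW), basal area increment (BAI) and blue
    intensity (BI) residual chronologies from raw ring measurements
    (Tucson/RWL and long-format CSV input): frequency-calibrated smoothing
    spline and Hugershoff growth-curve detrending, ratio indexing,
    autoregressive prewhitening, Tukey biweight chronology aggregation and the
    classical dendrochronological statistics (Rbar, EPS, mean sensitivity,
    serial autocorrelation), plus segment-based crossdating checks.
    Correlates residual chronologies against daily mean temperature aggregated
    over every cumulative window of 21 to 120 days spanning previous-year June
    through current-year October, with bootstrapped Pearson significance
    (percentile confidence intervals) and 15-year moving-window stability
    analysis. Includes a synthetic-data generator that produces daily
    temperature series and multi-tree ring datasets with a known injected
    climate-signal window for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
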