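Package: fishshift
Title: Environmental Drivers and Historical Distribution Shifts of
    Trawl-Surveyed Fish
Version: 1.0.0
Authors@R:
    person("Alex", "Doran", email = "alex.doran@example.org",
           role = c("aut", "cre"))
Description: Links the importance of environmental predictors (bottom
    temperature, bottom salinity, depth and sediment grain size) for fish
    species' catch rates to the species' historical distribution shifts.
    Predictor importance is scored as the deviance explained by
    single-covariate negative-binomial penalized-spline regressions of
    catch per unit effort; distribution change is measured between two
    five-year periods as the geodesic displacement of biomass-weighted
    centroids, the percentage change in CPUE-weighted 95% kernel-density
    range area, and shifts of the northern and southern range-edge
    latitudes.  Shift metrics are compared across strongest-predictor
    groups and across benthic, demersal and pelagic life-history groups
    with two-sided Wilcoxon rank-sum tests.  A stratified-random
    trawl-survey simulator with known environmental structure and known
    imposed range shifts makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
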