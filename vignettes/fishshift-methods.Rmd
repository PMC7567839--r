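---
title: "Methods: linking predictor importance to fish distribution shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking predictor importance to fish distribution shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`fishshift` implements a three-part analysis of bottom-trawl survey data.

1. **Predictor importance.** For each species, season and covariate
   $x \in \{$bottom temperature, bottom salinity, depth, sediment grain
   size$\}$, catch per unit effort is modeled with a single-covariate
   generalized additive model,
   $\mathrm{CPUE} \sim \mathrm{NB}(\mu, \theta)$,
   $\log \mu = s(x)$, where $s$ is a thin-plate penalized regression spline
   with basis dimension 10 and the smoothing parameter (and $\theta$) chosen
   by REML with an outer Newton optimizer. Importance is the deviance
   explained, $(D_0 - D_m)/D_0$, with $D_0$ the intercept-only deviance
   under the same family and $\theta$, and the *strongest predictor* of a
   species is the covariate with the largest deviance explained.
2. **Distribution-shift metrics.** For two five-year periods (1986–1990 and
   2014–2018) each species' distribution is summarized by its CPUE-weighted
   centroid, the area of the region holding 95% of its CPUE-weighted kernel
   density, and the minimum and maximum latitude of that region. Shifts are
   the great-circle distance between the two centroids, the percentage
   change in range area $100\,(A_2 - A_1)/A_1$, and the edge-latitude
   differences.
3. **Group comparisons.** Each shift metric is compared across
   strongest-predictor groups and across benthic / demersal / pelagic
   life-history groups with two-sided Wilcoxon rank-sum tests, pairwise.

A stratified-random survey simulator with known truth replaces the real
survey so that every stage is testable end to end.

# Deviance computations

The package owns the negative-binomial deviance,
$$D = 2\sum_i \left[ y_i \log\frac{y_i}{\mu_i}
  - (y_i + \theta) \log\frac{y_i + \theta}{\mu_i + \theta} \right],$$
with $y\log(y/\mu) = 0$ at $y = 0$. This equals twice the saturated-minus-
model log-likelihood difference for any nonnegative (also non-integer) $y$,
which is how the tests verify it; at $\theta \to \infty$ it converges to
the Poisson deviance. Engine deviances (mgcv) are recomputed with
`nb_deviance()` at fit time and must agree to $10^{-6}$ relative, so the
reported deviance explained never depends silently on a backend convention.
CPUE is treated as a raw nonnegative quantity (calibrated survey CPUE is
non-integer); the NB quasi-likelihood form needs no rounding or offset.
Deviance explained is clipped to $[0,1]$ (clipping is reported), and a
non-convergent or degenerate fit yields a missing cell rather than a zero,
because a zero would bias the strongest-predictor argmax. Exact ties in the
argmax are broken by the fixed covariate order (btemp, bsalin, depth,
grainsize).

# Range metrics: numerical choices

* **Geodesics** use the haversine formula on the IUGG mean sphere
  (R = 6371.0088 km); one degree of meridional arc is 111.195 km. An
  ellipsoidal geodesic differs by under 0.5% at the distances involved.
* **Centroids** are arithmetic weighted means of latitude and longitude;
  a guard refuses domains spanning 180 degrees or more of longitude (the
  study region is far from the antimeridian).
* **Kernel density** is a product-Gaussian weighted KDE evaluated on a
  regular lon/lat grid (default 200 x 200, padded by 3 bandwidths). The
  default bandwidth is the weighted Scott rule per axis,
  $h_j = \sigma_{j,w}\, n_\mathrm{eff}^{-1/6}$ with
  $n_\mathrm{eff} = (\sum w)^2 / \sum w^2$.
* **Variance correction.** Kernel smoothing inflates the variance of the
  estimated surface to $\sigma^2 + h^2$ per axis, so the area of a
  fixed-mass isopleth is biased upward by a factor of about
  $1 + n_\mathrm{eff}^{-1/3}$ — roughly +6% at $n = 5000$, which matters
  when the range area is a headline quantity. By default the kernel
  centers are therefore contracted toward the weighted centroid by
  $\sqrt{1 - h_j^2/\sigma_j^2}$ per axis, which restores the sample
  variance exactly and makes fixed-mass areas unbiased to first order for
  elliptical distributions (the variance-corrected smoothing of Silverman,
  1986, sec. 6.4). On 5000 unit-weight draws from a standard bivariate
  normal the 95% isopleth area then matches the analytic ellipse area
  $\pi \chi^2_{2,0.95} \approx 18.82$ to well within 5%, which the
  acceptance tests assert. `variance_correction = FALSE` restores the
  plain weighted KDE. Percentage range-area change is essentially
  insensitive to this choice (the factor cancels); absolute areas are not.
* **Isopleths** rank cells by density (stable order) and accumulate mass
  until the level is reached; equal-density cells beyond the cut are not
  pulled in, so a uniform 100-cell surface at level 0.95 selects exactly
  95 cells. Regions are nested in the level by construction.
* **Cell areas** are geodesic by default
  ($111.195^2 \cos(\mathrm{lat})\, \Delta\mathrm{lon}\, \Delta\mathrm{lat}$
  km²); a planar mode supports abstract data and the analytic oracle.
  Range areas are reported in km²; only the unit-free percentage change
  feeds the group comparisons.
* Bandwidth, grid resolution and isopleth level are exposed because range
  area is sensitive to them; the defaults above are documented rather than
  claimed to replicate any particular historical configuration.

# Rank-sum testing

`rank_sum_test()` computes the Mann–Whitney $U$ from midranks. For
tie-free samples with $n_1 + n_2 \le 12$ the two-sided p-value is exact by
enumeration of the null distribution of $U$; otherwise a normal
approximation with tie correction and continuity correction is used, and
identical samples return $p = 1$. The exact path is verified against
`wilcox.test`'s exact p-values exhaustively for all compositions with
$n_1 + n_2 \le 10$, and the approximate path reproduces `wilcox.test`'s
corrected p-values to machine precision, so reported values are
bit-reproducible. Holm adjustment across group pairs is computed and
reported alongside, but unadjusted p-values are primary: with three
groups and small $n$ per group, the unadjusted pairwise values are the
interpretable quantity, and both columns are always written so neither
mode is privileged.

# The synthetic survey generator

The generator is first-class, tested code; its defaults define the study
conditions used throughout the tests.

* **Design.** Ten strata (five 2° latitude bands x two 5° longitude bands
  over 35–45° N, 76–66° W), sampled every year 1986–2018 in spring and
  fall. Stations per stratum are `round(area x density)` (half away from
  zero, floor of one so no stratum ever breaks the coverage filter),
  uniform within the stratum box; the default density of 4.5e-4 stations
  per km² yields about 430 stations per seasonal survey, the scale of the
  Northeast US shelf bottom-trawl survey.
* **Environment.** Bottom temperature = 25 °C at 35° N minus 1.1 °C per
  degree latitude, plus 0.05 °C per year of linear warming (a strong but
  regionally realistic trend), a -3 °C spring offset, and a static
  cell-level anomaly (sd 0.6 °C) on a 0.1° grid with nearest-cell lookup.
  Salinity has a weaker latitudinal gradient, a small trend and a seeded
  interannual anomaly; depth (deeper offshore) is static; grain size is a
  static log-scale field with one coherent high-grain region in the
  southwest grading to low grain in the northeast plus cell-level
  patchiness (sd 0.3 on the log scale).
* **Species.** Expected CPUE is
  $\exp(b + \sum_c w_c \exp(-\tfrac12 ((x_c - o_c)/\beta_c)^2))$ with
  negative-binomial noise (default $\theta = 6$, moderately overdispersed).
  Twelve species ship by default, four per life-history group: pelagic
  (temperature weight 4, imposed shift 70 km/decade), demersal
  (temperature and grain size weights 1.8 each, 30 km/decade), benthic
  (grain-size weight 2.2, depth weight 0.8, anchored). These weights were
  fixed once, during generator design, so that the anchored species'
  centroid sampling noise stays in the single-digit kilometers while the
  grain-size signal still dominates the benthic importance scores; they
  are study conditions, not tuning knobs.
* **Imposed shifts.** A species' preferred temperature is defined as the
  deterministic temperature at latitude
  $\mathrm{anchor} + v (\mathrm{year} - 1986)$, with $v$ the configured
  poleward rate. $v = 0$ means the preferred temperature warms in
  lockstep with the water (the realized optimum stays put); $v > 0$ moves
  the realized optimum poleward at exactly $v$, and with the default
  periods the pelagic archetype's truth is 70 km/decade x 2.8 decades =
  196 km. Because the domain is finite and every species keeps a nonzero
  background density, the *expected-CPUE* centroid moves slightly slower
  than the imposed optimum (about -6% to -9% for the pelagic defaults);
  recovered shifts of ~175–180 km against the 196 km truth are therefore
  expected behavior of the estimator, not simulator error.
* **Determinism.** All randomness flows from one root seed through
  deterministic child seeds per stage, year, season and species, so any
  stage can be reproduced in isolation and identical configurations are
  byte-identical.

**What the generator does not emulate:** vessel or gear calibration,
day/night or within-season timing, spatial autocorrelation of catch noise
beyond the smooth niche structure, species interactions, fishing pressure,
demographic structure, and coastline/bathymetry geometry. Passing recovery
tests on these surveys demonstrates that the estimators recover known
structure of this kind; it does not certify behavior on the messier real
survey.

# Filters

Strata must have at least one haul in every (year, season) cell of the
span; species must be present (CPUE > 0 in some haul) in at least
`floor(0.5 x 33) = 16` years in *each* season, and show summed CPUE
strictly above 20 within both the first and last five-year windows in each
season. "Present" carries no density floor, the edge rule is a sum over
the window's hauls (the most literal reading of a per-window CPUE
threshold), and both thresholds are configurable. The floor (rather than
ceiling) of the presence fraction is deliberate: 16-of-33 is the
documented inclusion count for a 33-year span. Filters are idempotent and
monotone in their thresholds, which the tests assert.

# Problem sizes

The test suite and the acceptance script use: 100 seeded fall surveys for
shift recovery and the group-level pattern; 100 replicate fits at
n = 2000 (subsampled from full surveys) for predictor recovery, with 10
null replicates; 5000 draws for the KDE oracle; 10,000 replicates for the
rank-sum calibration; and one full fall survey (about 14,000 hauls, 48
single-covariate fits) for the default-scenario importance table. These
sizes give stable medians and rates while keeping a full run in the
single-digit minutes.

# Known limitations

* The KDE treats lon/lat as a plane with per-axis bandwidths and corrects
  only cell areas for latitude; at higher latitudes or continental extents
  an equal-area projection would be preferable.
* Centroids are arithmetic means in degrees, adequate for a ~10°-wide
  mid-latitude domain, biased for domains where meridian convergence
  matters.
* The NB smooths are univariate by design — importance is attributed one
  covariate at a time, so correlated covariates (depth and grain size,
  for instance) share credit in a way a joint model would not. That is a
  property of the method being implemented, preserved deliberately.
* With four species per group, the exact rank-sum test's smallest
  attainable two-sided p-value is 0.029; group comparisons at this scale
  are qualitative.
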