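# fishshift

Tools for asking why some fish species have shifted their distributions
under three decades of ocean warming while others have stayed put. The
package links **how strongly a species' catch rates are tied to each
environmental covariate** — bottom temperature, bottom salinity, depth,
sediment grain size — to **how far its distribution actually moved**
between two five-year periods (1986–1990 vs 2014–2018), and compares the
shift metrics across predictor groups and across benthic / demersal /
pelagic life histories. It is aimed at spatial ecologists working with
stratified-random bottom-trawl surveys (CPUE by haul, long format).

Because the real survey and substrate products cannot be bundled, the
package ships a fully seeded synthetic survey generator with known
environmental structure and known imposed range shifts, so every stage of
the analysis is testable against ground truth.

## The methods

* **Predictor importance** — per species, season and covariate, a
  single-covariate GAM: CPUE ~ s(x, k = 10) under a negative-binomial
  family with log link, REML smoothness selection (outer Newton), NAs
  dropped. Importance is deviance explained, (D₀ − Dₘ)/D₀, against the
  intercept-only model; the *strongest predictor* is the argmax across
  the four covariates. The NB deviance
  D = 2 Σ [y log(y/μ) − (y + θ) log((y + θ)/(μ + θ))] is computed in the
  package and cross-checked against the spline engine at every fit.
* **Shift metrics** — per species and season: biomass(CPUE)-weighted
  centroids for the two periods and their great-circle distance
  (R = 6371.0088 km); CPUE-weighted Gaussian-kernel density surfaces,
  the smallest region holding 95% of the density mass, its area (km²,
  latitude-corrected cells), 100·(A₂ − A₁)/A₁, and the region's
  southern/northern edge latitudes.
* **Group comparisons** — pairwise two-sided Wilcoxon rank-sum tests
  (exact by enumeration for small tie-free samples, otherwise
  tie- and continuity-corrected normal approximation), with optional Holm
  adjustment reported alongside.

See `vignettes/fishshift-methods.Rmd` for the full account of the model,
the generator's design, and the numerical conventions (bandwidths,
isopleth tie rules, variance correction of the KDE, seeds).

## Worked example

The `analysis/` scripts run the whole workflow on the default synthetic
scenario (33 years, 2 seasons, ~430 stations per seasonal survey, 12
species with imposed shifts of 196 / 84 / 0 km for pelagic / demersal /
benthic archetypes) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # survey + truth table
Rscript analysis/02_ingest.R        # strata/species inclusion filters
Rscript analysis/03_importance.R    # 96 NB-GAM fits, deviance explained
Rscript analysis/04_range_metrics.R # centroids, 95% ranges, edges
Rscript analysis/05_compare.R       # pairwise Wilcoxon tests
```

Stage 3 prints the strongest-predictor composition — substrate dominates
benthic species, temperature dominates pelagic species:

```
           btemp grainsize
  benthic      0         8
  demersal     7         1
  pelagic      8         0
```

Stage 4 prints the recovered shifts (fall; truth 0 / 84 / 196 km):

```
  life_history season   shift_km
       benthic   fall   5.071292
      demersal   fall  51.883381
       pelagic   fall 174.193544
```

Benthic species sit at their sampling-noise floor (~5 km), pelagic
species recover ~174 km of the imposed 196 km (the expected mild
attenuation from background biomass in a finite domain), and demersal
species — anchored by substrate but pushed by temperature — land in
between. Stage 5 then shows every life-history pair separated at the
smallest p attainable with four species per group (U = 0, p = 0.029).

The same computations are available programmatically:

```r
library(fishshift)
cfg <- simulation_config(seed = 1)
res <- run_all(pipeline_config(simulate = cfg), out_dir = "results/run")
head(res$metrics)
```

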