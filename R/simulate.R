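## Synthetic stratified-random trawl survey generator.
##
## The generator emulates the structure of a Northeast US shelf bottom-trawl
## survey: a fixed set of spatial strata sampled every year in spring and
## fall, with stations allocated proportionally to stratum area; smooth
## environmental fields (bottom temperature with a latitudinal gradient and a
## linear warming trend, bottom salinity with interannual variability, static
## depth and static patchy sediment grain size); and per-species catch rates
## that follow Gaussian niche responses on the log scale with
## negative-binomial observation noise.  Species carry a configurable true
## poleward range shift so that downstream recovery of centroid displacement
## is testable against known truth.

KM_PER_DEG_LAT <- pi * EARTH_RADIUS_KM / 180  # 111.1950 km

#' Define a survey stratum
#'
#' @param stratum_id character identifier.
#' @param lat_range,lon_range numeric length-2, degree bounds (non-degenerate).
#' @param area_km2 stratum area in km^2; station counts are proportional to it.
#' @param mean_depth nominal depth in m (informational only).
#' @return a `stratum_spec` list.
#' @export
stratum_spec <- function(stratum_id, lat_range, lon_range, area_km2,
                         mean_depth = NA_real_) {
  stopifnot(length(lat_range) == 2, length(lon_range) == 2)
  if (diff(lat_range) <= 0 || diff(lon_range) <= 0) {
    stop("stratum '", stratum_id, "': lat_range and lon_range must be non-degenerate")
  }
  if (!is.finite(area_km2) || area_km2 <= 0) {
    stop("stratum '", stratum_id, "': area_km2 must be positive")
  }
  structure(list(stratum_id = as.character(stratum_id),
                 lat_range = as.numeric(lat_range),
                 lon_range = as.numeric(lon_range),
                 area_km2 = as.numeric(area_km2),
                 mean_depth = mean_depth),
            class = "stratum_spec")
}

#' Define a simulated species
#'
#' The niche is a named list over the four covariates (`btemp`, `bsalin`,
#' `depth`, `grainsize`); each entry has `opt`, `breadth` (> 0) and `weight`
#' (>= 0).  Expected CPUE at a station is
#' `exp(baseline_log_cpue + sum_c weight_c * exp(-((x_c - opt_c)/breadth_c)^2 / 2))`.
#'
#' For `btemp` the optimum is dynamic: the species' preferred temperature is
#' defined as the deterministic (trend) temperature at latitude
#' `anchor_lat + v * (year - first year)`, where `v` is
#' `shift_km_per_decade` converted to degrees latitude per year.  With
#' `shift_km_per_decade = 0` the preferred temperature warms in lockstep with
#' the water and the realized thermal optimum stays at `anchor_lat`; with a
#' positive rate the realized optimum location moves poleward at exactly that
#' rate.  The `opt` entry of the `btemp` niche is therefore ignored and may
#' be `NA`.
#'
#' @param name species name.
#' @param life_history one of `"benthic"`, `"demersal"`, `"pelagic"`.
#' @param baseline_log_cpue intercept of the log mean CPUE.
#' @param niche named list of `list(opt, breadth, weight)` per covariate.
#' @param anchor_lat latitude (deg N) of the realized thermal optimum in the
#'   first survey year (only used when the `btemp` weight is positive).
#' @param shift_km_per_decade imposed poleward drift of the realized thermal
#'   optimum; 0 anchors the species.
#' @return a `species_profile` list.
#' @export
species_profile <- function(name, life_history, baseline_log_cpue,
                            niche = list(), anchor_lat = NA_real_,
                            shift_km_per_decade = 0) {
  life_history <- match.arg(life_history, c("benthic", "demersal", "pelagic"))
  known <- c("btemp", "bsalin", "depth", "grainsize")
  if (length(niche) && !all(names(niche) %in% known)) {
    stop("unknown niche covariate(s): ",
         paste(setdiff(names(niche), known), collapse = ", "))
  }
  for (cv in names(niche)) {
    n <- niche[[cv]]
    if (is.null(n$breadth) || n$breadth <= 0) {
      stop("species '", name, "', covariate '", cv, "': breadth must be > 0")
    }
    if (is.null(n$weight) || n$weight < 0) {
      stop("species '", name, "', covariate '", cv, "': weight must be >= 0")
    }
  }
  w_t <- if (!is.null(niche$btemp)) niche$btemp$weight else 0
  if (w_t > 0 && !is.finite(anchor_lat)) {
    stop("species '", name, "': anchor_lat required when btemp weight > 0")
  }
  structure(list(name = as.character(name), life_history = life_history,
                 baseline_log_cpue = baseline_log_cpue, niche = niche,
                 anchor_lat = anchor_lat,
                 shift_km_per_decade = shift_km_per_decade),
            class = "species_profile")
}

#' Configure a synthetic survey
#'
#' Defaults mirror the scale of the Northeast US shelf survey used throughout
#' the package: 33 survey years (1986-2018), spring and fall seasons, ten
#' strata spanning 35-45 deg N / 76-66 deg W, about 430 stations per
#' seasonal survey, a warming trend of 0.05 deg C per year, and twelve
#' species (four per life-history group).
#'
#' @param seed integer root seed; the same seed reproduces the identical
#'   survey exactly.
#' @param n_years number of consecutive survey years (>= 2).
#' @param year_min first survey year.
#' @param seasons character vector of season labels.
#' @param strata list of [stratum_spec()].
#' @param stations_per_unit_area stations per km^2 of stratum area.
#' @param warming_rate linear bottom-temperature trend, deg C per year.
#' @param species list of [species_profile()].
#' @param nb_dispersion negative-binomial size parameter theta (> 0);
#'   catch variance is `mu + mu^2 / theta`.
#' @param grid_res environmental grid resolution in degrees.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_years = 33L,
                              year_min = 1986L,
                              seasons = c("spring", "fall"),
                              strata = default_strata(),
                              stations_per_unit_area = 4.5e-4,
                              warming_rate = 0.05,
                              species = default_species(),
                              nb_dispersion = 6,
                              grid_res = 0.1) {
  if (n_years < 2) stop("n_years must be >= 2")
  if (!length(seasons)) stop("at least one season is required")
  if (!length(strata)) stop("at least one stratum is required")
  if (stations_per_unit_area <= 0) stop("stations_per_unit_area must be > 0")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (grid_res <= 0) stop("grid_res must be > 0")
  stopifnot(all(vapply(strata, inherits, TRUE, "stratum_spec")),
            all(vapply(species, inherits, TRUE, "species_profile")))
  structure(list(seed = as.integer(seed), n_years = as.integer(n_years),
                 year_min = as.integer(year_min), seasons = seasons,
                 strata = strata,
                 stations_per_unit_area = stations_per_unit_area,
                 warming_rate = warming_rate, species = species,
                 nb_dispersion = nb_dispersion, grid_res = grid_res),
            class = "simulation_config")
}

#' Default strata: five 2-degree latitude bands by two 5-degree longitude
#' bands over 35-45 N, 76-66 W, with areas from the spherical box area.
#' @return list of [stratum_spec()].
#' @export
default_strata <- function() {
  out <- list()
  k <- 0
  for (i in 0:4) {
    for (j in 0:1) {
      k <- k + 1
      latr <- c(35 + 2 * i, 37 + 2 * i)
      lonr <- c(-76 + 5 * j, -71 + 5 * j)
      area <- KM_PER_DEG_LAT^2 * diff(latr) * diff(lonr) *
        cos(mean(latr) * pi / 180)
      out[[k]] <- stratum_spec(sprintf("S%02d", k), latr, lonr, area,
                               mean_depth = 30 + 55 * j)
    }
  }
  out
}

#' Default species pool: four pelagic (temperature-dominant, shifting 70
#' km/decade), four demersal (temperature + grain size, 30 km/decade) and
#' four benthic (grain-size-dominant, anchored).
#' @return list of [species_profile()].
#' @export
default_species <- function() {
  pel <- function(i, lat0) species_profile(
    sprintf("pelagic_%d", i), "pelagic", baseline_log_cpue = 1.6,
    niche = list(btemp = list(opt = NA, breadth = 2.2, weight = 4),
                 depth = list(opt = 70, breadth = 70, weight = 0.6)),
    anchor_lat = lat0, shift_km_per_decade = 70)
  dem <- function(i, lat0, gopt) species_profile(
    sprintf("demersal_%d", i), "demersal", baseline_log_cpue = 1.8,
    niche = list(btemp = list(opt = NA, breadth = 2.5, weight = 1.8),
                 grainsize = list(opt = gopt, breadth = 0.5, weight = 1.8)),
    anchor_lat = lat0, shift_km_per_decade = 30)
  ben <- function(i, gopt, gbr, dopt) species_profile(
    sprintf("benthic_%d", i), "benthic", baseline_log_cpue = 1.8,
    niche = list(grainsize = list(opt = gopt, breadth = gbr, weight = 2.2),
                 depth = list(opt = dopt, breadth = 60, weight = 0.8)),
    shift_km_per_decade = 0)
  c(lapply(1:4, function(i) pel(i, c(38, 38.5, 39, 39.5)[i])),
    lapply(1:4, function(i) dem(i, c(39, 39.5, 40, 40.5)[i],
                                c(1.0, 1.2, 1.4, 1.1)[i])),
    list(ben(1, 2.2, 0.90, 60), ben(2, 2.0, 0.90, 80),
         ben(3, 0.50, 0.30, 120), ben(4, 0.55, 0.33, 150)))
}

season_offset <- function(season) {
  off <- c(spring = -3, fall = 0)
  out <- unname(off[season])
  out[is.na(out)] <- 0
  out
}

#' Generate the environmental fields for a configuration
#'
#' Bottom temperature follows a monotone latitudinal gradient (colder
#' poleward) plus a linear warming trend and a static cell-level anomaly;
#' bottom salinity has a latitudinal gradient, a weak trend and a seeded
#' interannual anomaly; depth (deeper offshore) and sediment grain size
#' (patchy, log-scale) are static.  Fields live on a regular lon/lat grid
#' with nearest-cell lookup.
#'
#' @param config a [simulation_config()].
#' @return an `env_field` object.
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  lat_r <- range(unlist(lapply(config$strata, `[[`, "lat_range")))
  lon_r <- range(unlist(lapply(config$strata, `[[`, "lon_range")))
  res <- config$grid_res
  lon <- seq(lon_r[1] + res / 2, lon_r[2] - res / 2, by = res)
  lat <- seq(lat_r[1] + res / 2, lat_r[2] - res / 2, by = res)
  if (length(lon) < 2 || length(lat) < 2) {
    stop("environmental grid is degenerate; decrease grid_res")
  }
  nlon <- length(lon); nlat <- length(lat)
  noise <- with_seed(derive_seed(config$seed, 11L), {
    list(t = matrix(stats::rnorm(nlon * nlat, 0, 0.6), nlon, nlat),
         s = matrix(stats::rnorm(nlon * nlat, 0, 0.25), nlon, nlat),
         d = matrix(stats::rnorm(nlon * nlat, 0, 18), nlon, nlat),
         g = matrix(stats::rnorm(nlon * nlat, 0, 0.3), nlon, nlat))
  })
  salin_anom <- with_seed(derive_seed(config$seed, 12L),
                          stats::rnorm(config$n_years, 0, 0.15))
  latm <- matrix(lat, nlon, nlat, byrow = TRUE)
  lonm <- matrix(lon, nlon, nlat)
  depth <- pmax(30 + 22 * (lonm - lon_r[1]) + noise$d, 10)  # keeps dim()
  ## long-wavelength additive structure: a single high-grain region in the
  ## southwest grading to low grain in the northeast, plus cell-level
  ## patchiness, so a grain-size specialist occupies one coherent patch
  grain <- exp(0.55 * cos(2 * pi * (lonm - lon_r[1]) / 22) +
                 0.35 * cos(2 * pi * (latm - lat_r[1]) / 24) + noise$g)
  structure(list(lon = lon, lat = lat, res = res,
                 lat0 = lat_r[1], lon0 = lon_r[1],
                 year_min = config$year_min, n_years = config$n_years,
                 warming_rate = config$warming_rate,
                 t_base = 25, t_grad = 1.1,
                 s_base = 36, s_grad = 0.25, s_trend = 0.005,
                 noise_t = noise$t, noise_s = noise$s,
                 depth = depth, grain = grain,
                 salin_anom = salin_anom),
            class = "env_field")
}

## deterministic (trend-only) bottom temperature, no cell anomaly
btemp_trend <- function(env, lat, year, season) {
  env$t_base - env$t_grad * (lat - env$lat0) +
    env$warming_rate * (year - env$year_min) + season_offset(season)
}

env_cell_index <- function(env, lon, lat) {
  i <- pmin(pmax(round((lon - env$lon[1]) / env$res) + 1, 1), length(env$lon))
  j <- pmin(pmax(round((lat - env$lat[1]) / env$res) + 1, 1), length(env$lat))
  pad <- env$res  # allow lookups only within one cell of the grid hull
  if (any(lon < env$lon[1] - pad - env$res / 2 | lon > env$lon[length(env$lon)] + pad + env$res / 2 |
            lat < env$lat[1] - pad - env$res / 2 | lat > env$lat[length(env$lat)] + pad + env$res / 2)) {
    stop("station outside the environmental grid")
  }
  cbind(i, j)
}

#' Look up covariates at point locations
#'
#' @param env an `env_field`.
#' @param lon,lat coordinate vectors (degrees).
#' @param year survey year; `season` season label.
#' @return data.frame with columns `btemp`, `bsalin`, `depth`, `grainsize`.
#' @export
env_at <- function(env, lon, lat, year, season) {
  ij <- env_cell_index(env, lon, lat)
  yi <- year - env$year_min + 1
  if (yi < 1 || yi > env$n_years) stop("year outside the simulated span")
  data.frame(
    btemp = btemp_trend(env, lat, year, season) + env$noise_t[ij],
    bsalin = env$s_base - env$s_grad * (lat - env$lat0) +
      env$s_trend * (year - env$year_min) + env$salin_anom[yi] +
      env$noise_s[ij],
    depth = env$depth[ij],
    grainsize = env$grain[ij])
}

#' Per-cell field values for one year and season
#'
#' @inheritParams env_at
#' @return data.frame with one row per grid cell (`lon`, `lat`, covariates).
#' @export
env_values <- function(env, year, season) {
  g <- expand.grid(lon = env$lon, lat = env$lat, KEEP.OUT.ATTRS = FALSE)
  cbind(g, env_at(env, g$lon, g$lat, year, season))
}

#' Allocate stations for one seasonal survey
#'
#' Station count per stratum is `round(area * stations_per_unit_area)`
#' (half away from zero) with a floor of one station, and stations are
#' uniform within the stratum's lat/lon bounds.  Placement is seeded from
#' the configuration seed, the year and the season, so every (year, season)
#' survey is reproducible in isolation.
#'
#' @param config a [simulation_config()].
#' @param year,season survey year and season label.
#' @return data.frame with columns `stratum`, `lat`, `lon`.
#' @export
sample_stations <- function(config, year, season) {
  stopifnot(inherits(config, "simulation_config"))
  si <- match(season, config$seasons)
  if (is.na(si)) stop("unknown season: ", season)
  seed <- derive_seed(config$seed, year, si, 1L)
  with_seed(seed, {
    blocks <- lapply(config$strata, function(st) {
      n <- max(1L, as.integer(round_half_up(st$area_km2 *
                                              config$stations_per_unit_area)))
      data.frame(stratum = st$stratum_id,
                 lat = stats::runif(n, st$lat_range[1], st$lat_range[2]),
                 lon = stats::runif(n, st$lon_range[1], st$lon_range[2]))
    })
    do.call(rbind, blocks)
  })
}

## Gaussian niche contribution of one covariate on the log-mean scale
niche_term <- function(x, opt, breadth, weight) {
  weight * exp(-0.5 * ((x - opt) / breadth)^2)
}

## realized thermal-optimum latitude for a species in a given year
optimum_latitude <- function(profile, year, year_min) {
  v_deg_per_year <- profile$shift_km_per_decade / 10 / KM_PER_DEG_LAT
  profile$anchor_lat + v_deg_per_year * (year - year_min)
}

#' Expected (noiseless) CPUE for a species at given covariates
#'
#' @param profile a [species_profile()].
#' @param covars data.frame with `btemp`, `bsalin`, `depth`, `grainsize`.
#' @param env the `env_field` (needed to resolve the dynamic thermal optimum).
#' @param year,season survey year and season.
#' @return vector of mean CPUE values.
#' @export
expected_cpue <- function(profile, covars, env, year, season) {
  eta <- rep(profile$baseline_log_cpue, nrow(covars))
  for (cv in names(profile$niche)) {
    n <- profile$niche[[cv]]
    if (n$weight == 0) next
    opt <- if (cv == "btemp") {
      btemp_trend(env, optimum_latitude(profile, year, env$year_min),
                  year, season)
    } else {
      n$opt
    }
    eta <- eta + niche_term(covars[[cv]], opt, n$breadth, n$weight)
  }
  exp(eta)
}

#' Draw negative-binomial catches for one species at a set of stations
#'
#' @param profile a [species_profile()].
#' @param stations data.frame with `lat`, `lon` (as from [sample_stations()]).
#' @param env an `env_field`.
#' @param year,season survey year and season.
#' @param nb_dispersion NB size parameter theta.
#' @param seed integer seed for the draws.
#' @return numeric vector of CPUE values (>= 0).
#' @export
simulate_cpue <- function(profile, stations, env, year, season,
                          nb_dispersion, seed) {
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  covars <- env_at(env, stations$lon, stations$lat, year, season)
  mu <- expected_cpue(profile, covars, env, year, season)
  with_seed(seed, stats::rnbinom(length(mu), size = nb_dispersion, mu = mu))
}

#' Generate a full synthetic survey
#'
#' Runs the stratified station allocation and per-species catch simulation
#' over every year and season of the configuration and returns the
#' long-format haul table together with a truth table recording each
#' species' imposed shift.
#'
#' @param config a [simulation_config()].
#' @param truth_periods a [period_spec()] used to express the imposed shift
#'   as a single km value between the two period midpoints.
#' @return list with elements `survey` (data.frame with columns `haul_id`,
#'   `year`, `season`, `stratum`, `lat`, `lon`, `depth`, `btemp`, `bsalin`,
#'   `grainsize`, `species`, `cpue`), `truth` (per species: life history,
#'   imposed rate, anchor latitude, `true_shift_km` between period
#'   midpoints), `path` (per species x year realized optimum latitude) and
#'   `env` (the `env_field`).
#' @export
build_survey <- function(config, truth_periods = period_spec()) {
  stopifnot(inherits(config, "simulation_config"))
  env <- generate_environment(config)
  years <- config$year_min + seq_len(config$n_years) - 1L
  sp_names <- vapply(config$species, `[[`, "", "name")
  blocks <- vector("list", length(years) * length(config$seasons))
  b <- 0
  for (year in years) {
    for (si in seq_along(config$seasons)) {
      season <- config$seasons[si]
      st <- sample_stations(config, year, season)
      covars <- env_at(env, st$lon, st$lat, year, season)
      haul_id <- sprintf("%d_%s_%03d", year, season, seq_len(nrow(st)))
      per_sp <- lapply(seq_along(config$species), function(k) {
        prof <- config$species[[k]]
        mu <- expected_cpue(prof, covars, env, year, season)
        y <- with_seed(derive_seed(config$seed, year, si, k, 3L),
                       stats::rnbinom(length(mu), size = config$nb_dispersion,
                                      mu = mu))
        data.frame(haul_id = haul_id, year = year, season = season,
                   stratum = st$stratum, lat = st$lat, lon = st$lon,
                   depth = covars$depth, btemp = covars$btemp,
                   bsalin = covars$bsalin, grainsize = covars$grainsize,
                   species = sp_names[k], cpue = as.numeric(y))
      })
      b <- b + 1
      blocks[[b]] <- do.call(rbind, per_sp)
    }
  }
  survey <- do.call(rbind, blocks)
  rownames(survey) <- NULL
  mid1 <- mean(truth_periods$period1)
  mid2 <- mean(truth_periods$period2)
  truth <- data.frame(
    species = sp_names,
    life_history = vapply(config$species, `[[`, "", "life_history"),
    shift_km_per_decade = vapply(config$species, `[[`, 0, "shift_km_per_decade"),
    anchor_lat = vapply(config$species, `[[`, 0, "anchor_lat"),
    true_shift_km = vapply(config$species, `[[`, 0, "shift_km_per_decade") *
      (mid2 - mid1) / 10)
  path <- expand.grid(species = sp_names, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  path$opt_lat <- mapply(function(sp, yr) {
    prof <- config$species[[match(sp, sp_names)]]
    if (is.finite(prof$anchor_lat)) {
      optimum_latitude(prof, yr, config$year_min)
    } else {
      NA_real_
    }
  }, path$species, path$year)
  list(survey = survey, truth = truth, path = path, env = env)
}
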