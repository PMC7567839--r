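test_that("the same seed reproduces the identical survey", {
  a <- build_survey(fixture_config(seed = 7))
  b <- build_survey(fixture_config(seed = 7))
  expect_identical(a$survey, b$survey)
  expect_identical(a$env$grain, b$env$grain)
  c <- build_survey(fixture_config(seed = 8))
  expect_false(identical(a$survey$cpue, c$survey$cpue))
})

test_that("temperature field warms linearly and only via the trend", {
  cfg0 <- fixture_config(seed = 3)
  cfg0$warming_rate <- 0
  env0 <- generate_environment(cfg0)
  y1 <- env_values(env0, cfg0$year_min, "fall")
  y2 <- env_values(env0, cfg0$year_min + cfg0$n_years - 1, "fall")
  expect_equal(y1$btemp, y2$btemp)

  cfg <- simulation_config(seed = 3, warming_rate = 0.05, grid_res = 0.5)
  env <- generate_environment(cfg)
  first <- env_values(env, 1986, "fall")
  last <- env_values(env, 2018, "fall")
  expect_equal(mean(last$btemp) - mean(first$btemp), 32 * 0.05,
               tolerance = 1e-10)
  ## depth and grain size are static by construction
  expect_equal(first$depth, last$depth)
  expect_equal(first$grainsize, last$grainsize)
  expect_true(all(first$grainsize > 0))
  ## colder poleward: trend temperature decreases with latitude
  expect_lt(cor(first$lat, first$btemp), -0.9)
})

test_that("stations are allocated proportionally to stratum area", {
  strata <- list(stratum_spec("a", c(38, 39), c(-71, -70), 100),
                 stratum_spec("b", c(39, 40), c(-71, -70), 300))
  cfg <- simulation_config(seed = 1, strata = strata,
                           stations_per_unit_area = 0.02,
                           species = list(), grid_res = 0.2)
  st <- sample_stations(cfg, 1986, "fall")
  expect_equal(unname(table(st$stratum)["a"]), 2)
  expect_equal(unname(table(st$stratum)["b"]), 6)
  ## containment within stratum bounds
  a <- st[st$stratum == "a", ]
  expect_true(all(a$lat >= 38 & a$lat <= 39 & a$lon >= -71 & a$lon <= -70))

  ## proportionality up to rounding for arbitrary areas, floor of one
  set.seed(42)
  for (i in 1:20) {
    areas <- runif(2, 10, 2000)
    strata <- list(stratum_spec("a", c(38, 39), c(-71, -70), areas[1]),
                   stratum_spec("b", c(39, 40), c(-71, -70), areas[2]))
    cfg <- simulation_config(seed = i, strata = strata,
                             stations_per_unit_area = 0.01,
                             species = list(), grid_res = 0.2)
    st <- sample_stations(cfg, 1990, "fall")
    n <- table(st$stratum)
    expect_equal(unname(n["a"]), max(1, floor(areas[1] * 0.01 + 0.5)))
    expect_equal(unname(n["b"]), max(1, floor(areas[2] * 0.01 + 0.5)))
  }
})

test_that("catch noise is negative binomial with the configured size", {
  cfg <- fixture_config(seed = 11)
  env <- generate_environment(cfg)
  flat <- species_profile("flat", "demersal", baseline_log_cpue = 2)
  one_station <- data.frame(stratum = "A", lat = 38, lon = -72)
  stations <- one_station[rep(1, 1e5), ]
  ## flat niche: every station's mean is exp(baseline)
  covars <- env_at(env, stations$lon, stations$lat, 2012, "fall")
  expect_equal(expected_cpue(flat, covars, env, 2012, "fall"),
               rep(exp(2), 1e5))
  y <- simulate_cpue(flat, stations, env, 2012, "fall",
                     nb_dispersion = 2, seed = 99)
  mu <- exp(2)
  expect_equal(mean(y), mu, tolerance = 0.02)
  expect_equal(var(y), mu + mu^2 / 2, tolerance = 0.05)
  ## Poisson limit: variance/mean ratio tends to 1 as theta grows
  y2 <- simulate_cpue(flat, stations, env, 2012, "fall",
                      nb_dispersion = 1e6, seed = 100)
  expect_equal(var(y2) / mean(y2), 1, tolerance = 0.02)
})

test_that("expected-CPUE centroids move at the imposed rate (or not at all)", {
  cfg <- simulation_config(seed = 5, grid_res = 0.2)
  env <- generate_environment(cfg)
  grid <- env_values(env, 1986, "fall")
  centroid_of <- function(profile, year) {
    cv <- env_values(env, year, "fall")
    mu <- expected_cpue(profile, cv, env, year, "fall")
    weighted_centroid(cv$lat, cv$lon, mu)
  }
  ## anchored benthic archetype: static covariates, static expectation
  ben <- default_species()[[9]]
  expect_identical(ben$life_history, "benthic")
  expect_equal(centroid_of(ben, 1986), centroid_of(ben, 2018),
               tolerance = 1e-12)
  ## shifting pelagic archetype: centroid of the expectation surface moves
  ## poleward at close to the configured rate (finite-domain background
  ## biomass attenuates it slightly)
  pel <- default_species()[[1]]
  c1 <- centroid_of(pel, 1986)
  c2 <- centroid_of(pel, 2018)
  moved <- (c2["lat"] - c1["lat"]) * pi * 6371.0088 / 180
  imposed <- 70 * 3.2  # km/decade over 32 years
  expect_gt(moved, 0)
  expect_equal(unname(moved), imposed, tolerance = 0.12)
})

test_that("build_survey output matches the schema and the truth table", {
  cfg <- fixture_config(seed = 2)
  sim <- build_survey(cfg)
  n_stations <- nrow(sample_stations(cfg, cfg$year_min, "fall"))
  expect_equal(nrow(sim$survey),
               n_stations * cfg$n_years * 2 * length(cfg$species))
  expect_named(sim$survey, c("haul_id", "year", "season", "stratum", "lat",
                             "lon", "depth", "btemp", "bsalin", "grainsize",
                             "species", "cpue"))
  expect_false(anyDuplicated(sim$survey[c("haul_id", "species")]) > 0)
  expect_true(all(sim$survey$cpue >= 0))

  ## truth: anchored species 0 km; default periods give 2.8 decades
  tr <- build_survey(simulation_config(seed = 1, n_years = 33,
                                       species = default_species()[c(1, 9)],
                                       strata = default_strata()[1:2],
                                       stations_per_unit_area = 1e-5,
                                       grid_res = 0.5))$truth
  expect_equal(tr$true_shift_km[tr$life_history == "benthic"], 0)
  expect_equal(tr$true_shift_km[tr$life_history == "pelagic"], 2.8 * 70)
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_years = 1), "n_years")
  expect_error(simulation_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(simulation_config(strata = list()), "stratum")
  expect_error(stratum_spec("x", c(40, 40), c(-71, -70), 10), "non-degenerate")
  expect_error(stratum_spec("x", c(39, 40), c(-71, -70), -1), "positive")
  expect_error(species_profile("x", "benthic", 1,
                               niche = list(depth = list(opt = 1, breadth = 0,
                                                         weight = 1))),
               "breadth")
  cfg <- fixture_config(1)
  env <- generate_environment(cfg)
  expect_error(env_at(env, -50, 39, 2012, "fall"), "outside")
})
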