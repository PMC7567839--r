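# Shared helpers: independent oracles and cached heavy simulations.

## Independent NB log-likelihood, written directly from the density
## (not from the deviance formula), for the deviance identity oracle.
nb_loglik_oracle <- function(y, mu, theta) {
  term_y <- ifelse(y > 0, y * log(mu / (theta + mu)), 0)
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * log(theta / (theta + mu)) + term_y)
}

## saturated NB log-likelihood (mu = y), y = 0 handled by the limit
nb_loglik_saturated <- function(y, theta) {
  mu <- pmax(y, 1e-300)
  term_y <- ifelse(y > 0, y * log(y / (theta + y)), 0)
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * log(theta / (theta + y)) + term_y)
}

## Poisson deviance, independent closed form
poisson_deviance_oracle <- function(y, mu) {
  2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
}

## toy survey table builder for the filter tests
toy_survey <- function(rows) {
  defaults <- data.frame(haul_id = NA_character_, year = NA_integer_,
                         season = "fall", stratum = "S1", lat = 40,
                         lon = -70, depth = 50, btemp = 10, bsalin = 34,
                         grainsize = 1, species = "sp", cpue = 0)
  out <- do.call(rbind, lapply(rows, function(r) {
    d <- defaults
    for (nm in names(r)) d[[nm]] <- r[[nm]]
    d
  }))
  out$haul_id <- ifelse(is.na(out$haul_id),
                        paste0("h", seq_len(nrow(out))), out$haul_id)
  out
}

## centroid shift (first vs last five years) for every species of a
## fall-only default survey; cached because two acceptance checks share it
shift_matrix_cache <- new.env(parent = emptyenv())
default_shift_matrix <- function(n_seeds = 100) {
  key <- paste0("s", n_seeds)
  if (!is.null(shift_matrix_cache[[key]])) return(shift_matrix_cache[[key]])
  one <- function(seed) {
    cfg <- simulation_config(seed = seed, seasons = "fall")
    d <- build_survey(cfg)$survey
    vapply(unique(d$species), function(sp) {
      ds <- d[d$species == sp, ]
      d1 <- ds[ds$year <= 1990, ]
      d2 <- ds[ds$year >= 2014, ]
      c1 <- weighted_centroid(d1$lat, d1$lon, d1$cpue)
      c2 <- weighted_centroid(d2$lat, d2$lon, d2$cpue)
      geodesic_km(c1["lat"], c1["lon"], c2["lat"], c2["lon"])
    }, numeric(1))
  }
  S <- vapply(seq_len(n_seeds), one, numeric(12))
  shift_matrix_cache[[key]] <- S
  S
}
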