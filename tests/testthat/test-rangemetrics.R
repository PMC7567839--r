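uniform_surface <- function(n_side = 10) {
  m <- matrix(1 / n_side^2, n_side, n_side)
  structure(list(lon = seq_len(n_side), lat = seq_len(n_side), mass = m,
                 dens = m, area = matrix(1, n_side, n_side), h = c(1, 1)),
            class = "density_surface")
}

test_that("weighted centroid is the weighted mean of coordinates", {
  expect_equal(weighted_centroid(40, -70, 5), c(lat = 40, lon = -70))
  expect_equal(weighted_centroid(c(40, 42), c(-70, -70), c(1, 1)),
               c(lat = 41, lon = -70))
  expect_equal(weighted_centroid(c(40, 42), c(-70, -70), c(1, 3)),
               c(lat = 41.5, lon = -70))
  ## brute-force agreement on random data
  set.seed(5)
  lat <- runif(200, 35, 45); lon <- runif(200, -76, -66)
  w <- rexp(200)
  got <- weighted_centroid(lat, lon, w)
  expect_equal(unname(got["lat"]), sum(w * lat) / sum(w), tolerance = 1e-12)
  expect_equal(unname(got["lon"]), sum(w * lon) / sum(w), tolerance = 1e-12)
  expect_error(weighted_centroid(c(40, 41), c(-70, -71), c(0, 0)),
               "all weights")
  expect_error(weighted_centroid(c(40, 41), c(100, -100), c(1, 1)), "180")
})

test_that("geodesic distance matches the spherical oracles", {
  expect_equal(geodesic_km(40, -70, 40, -70), 0)
  expect_equal(geodesic_km(40, -70, 41, -70), 111.195, tolerance = 1e-5)
  set.seed(8)
  p <- cbind(runif(100, -80, 80), runif(100, -170, 170))
  q <- cbind(runif(100, -80, 80), runif(100, -170, 170))
  d1 <- geodesic_km(p[, 1], p[, 2], q[, 1], q[, 2])
  d2 <- geodesic_km(q[, 1], q[, 2], p[, 1], p[, 2])
  expect_equal(d1, d2)
  ## independent engine: geosphere's spherical law of cosines
  d3 <- geosphere::distCosine(cbind(p[, 2], p[, 1]), cbind(q[, 2], q[, 1]),
                              r = 6371008.8) / 1000
  big <- d1 > 1
  expect_equal(d1[big], d3[big], tolerance = 1e-6)
  expect_error(geodesic_km(95, 0, 0, 0), "latitude")
})

test_that("weighted KDE mass is normalized, scale-invariant, delta-limited", {
  set.seed(12)
  lon <- runif(300, -72, -70); lat <- runif(300, 38, 40)
  w <- rexp(300)
  s <- weighted_kde(lon, lat, w, grid_n = 80)
  expect_equal(sum(s$mass), 1, tolerance = 1e-9)
  expect_true(all(s$mass >= 0))
  s2 <- weighted_kde(lon, lat, 2 * w, grid_n = 80)
  expect_equal(s$mass, s2$mass, tolerance = 1e-12)
  ## all weight on one point concentrates the mass near that point
  sd <- weighted_kde(c(-71, -70.5), c(39, 39.5), c(1, 0),
                     bandwidth = c(0.05, 0.05), grid_n = 120)
  near <- outer((sd$lon + 71)^2, (sd$lat - 39)^2, "+") < (3 * 0.05)^2
  expect_gt(sum(sd$mass[near]), 0.99)
  expect_error(weighted_kde(c(-71, -71), c(39, 39), c(1, 1), grid_n = 20),
               "degenerate|bandwidth")
})

test_that("isopleth takes the smallest region reaching the mass level", {
  u <- uniform_surface(10)
  iso <- isopleth(u, 0.95)
  expect_equal(sum(iso$mask), 95)
  expect_equal(iso$area, 95)
  ## all mass in one cell
  one <- uniform_surface(10)
  one$mass[] <- 0; one$mass[3, 7] <- 1
  one$dens <- one$mass
  iso1 <- isopleth(one, 0.95)
  expect_equal(sum(iso1$mask), 1)
  expect_true(iso1$mask[3, 7])
  expect_equal(iso1$area, 1)
  ## monotone nesting in the level
  set.seed(3)
  s <- weighted_kde(runif(200, -72, -70), runif(200, 38, 40), rexp(200),
                    grid_n = 60)
  expect_gte(isopleth(s, 0.99)$area, isopleth(s, 0.95)$area)
  expect_gte(isopleth(s, 0.95)$area, isopleth(s, 0.50)$area)
  expect_error(isopleth(s, 1.2), "level")
})

test_that("range extent reports the region's latitude span", {
  u <- uniform_surface(10)
  m <- matrix(FALSE, 10, 10); m[4, 6] <- TRUE
  expect_equal(range_extent(u, m), c(south = 6, north = 6))
  m[9, 2] <- TRUE
  expect_equal(range_extent(u, m), c(south = 2, north = 6))
  expect_error(range_extent(u, matrix(FALSE, 10, 10)), "empty")
})

test_that("range metrics are invariant where the distribution is static", {
  set.seed(77)
  base <- data.frame(lat = runif(400, 37, 42), lon = runif(400, -74, -69),
                     cpue = rnbinom(400, size = 5, mu = 8))
  rec <- rbind(cbind(base, year = rep(1986:1990, each = 80)),
               cbind(base, year = rep(2014:2018, each = 80)))
  m <- compute_range_metrics(rec, grid_n = 100)
  expect_equal(m$shift_km, 0, tolerance = 1e-9)
  expect_equal(m$pct_area_change, 0, tolerance = 1e-9)
  expect_equal(m$d_north, 0)
  expect_equal(m$d_south, 0)
  expect_equal(m$pct_area_change,
               100 * (m$area2_km2 - m$area1_km2) / m$area1_km2)
  expect_lte(m$south1, m$north1)

  ## uniform rescaling of CPUE changes nothing
  rec2 <- rec; rec2$cpue <- rec2$cpue * 7
  m2 <- compute_range_metrics(rec2, grid_n = 100)
  m$n1 <- m2$n1  # identical anyway
  expect_equal(m2$shift_km, m$shift_km)
  expect_equal(m2$area1_km2, m$area1_km2, tolerance = 1e-9)

  ## a period without positive catch yields NA metrics with a reason
  rec3 <- rec; rec3$cpue[rec3$year >= 2014] <- 0
  m3 <- compute_range_metrics(rec3)
  expect_true(is.na(m3$shift_km))
  expect_match(m3$reason, "period 2")
})

test_that("a poleward-shifted species shows positive edge displacement", {
  ## two synthetic periods: the same cloud translated 2 degrees north
  set.seed(41)
  n <- 600
  lat1 <- rnorm(n, 39, 0.8); lon <- rnorm(n, -71, 0.8)
  w <- rexp(n)
  rec <- rbind(
    data.frame(year = 1988, lat = lat1, lon = lon, cpue = w),
    data.frame(year = 2016, lat = lat1 + 2, lon = lon, cpue = w))
  m <- compute_range_metrics(rec, grid_n = 100)
  expect_equal(m$shift_km, 2 * 111.195, tolerance = 0.01)
  expect_gt(m$d_north, 1.5)
  expect_gt(m$d_south, 1.5)
  ## the translated cloud covers the same lon/lat footprint, but geodesic
  ## cell areas shrink with cos(latitude), so the area drops a few percent
  expect_lt(abs(m$pct_area_change), 5)
  expect_lt(m$pct_area_change, 0)
})
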