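## Distribution-shift metrics: biomass-weighted centroids, geodesic centroid
## displacement, CPUE-weighted Gaussian kernel density surfaces, 95%
## kernel-density range areas and range-edge latitudes, compared between two
## multi-year periods.

#' Define the two comparison periods
#'
#' @param period1,period2 integer length-2 year ranges (inclusive); defaults
#'   are the first and last five survey years, 1986-1990 and 2014-2018.
#' @return a `period_spec` list.
#' @export
period_spec <- function(period1 = c(1986, 1990), period2 = c(2014, 2018)) {
  stopifnot(length(period1) == 2, length(period2) == 2,
            period1[1] <= period1[2], period2[1] <= period2[2])
  if (period1[2] >= period2[1] && period2[2] >= period1[1]) {
    stop("periods must not overlap")
  }
  structure(list(period1 = as.integer(period1),
                 period2 = as.integer(period2)),
            class = "period_spec")
}

#' Biomass-weighted centroid of haul positions
#'
#' Arithmetic weighted mean of latitude and longitude.  The domain is
#' assumed to be far from the antimeridian; a guard refuses longitude spans
#' of 180 degrees or more.
#'
#' @param lat,lon coordinate vectors (degrees).
#' @param w nonnegative weights (CPUE); must not sum to zero.
#' @return named vector `c(lat, lon)`.
#' @export
weighted_centroid <- function(lat, lon, w) {
  stopifnot(length(lat) == length(lon), length(lat) == length(w))
  if (any(w < 0)) stop("weights must be nonnegative")
  if (sum(w) <= 0) stop("centroid undefined: all weights are zero")
  if (diff(range(lon)) >= 180) stop("longitude span >= 180 degrees")
  c(lat = sum(w * lat) / sum(w), lon = sum(w * lon) / sum(w))
}

#' Great-circle distance in km
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean).  An
#' ellipsoidal geodesic differs from this sphere by well under 0.5% at the
#' scales involved.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees (vectorized).
#' @return distance(s) in km.
#' @export
geodesic_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90)) stop("latitude outside [-90, 90]")
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

## weighted standard deviation
wsd <- function(x, w) {
  m <- sum(w * x) / sum(w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

#' CPUE-weighted Gaussian kernel density surface
#'
#' Product Gaussian kernels with per-axis bandwidths on a regular lon/lat
#' grid.  The default bandwidth is the weighted Scott rule per axis,
#' `h_j = sigma_j,w * n_eff^(-1/6)` with effective sample size
#' `n_eff = (sum w)^2 / sum(w^2)`.  The returned cell masses are normalized
#' to sum to one; cell areas are either geodesic
#' (`111.195^2 * cos(lat) * dlon * dlat` km^2) or planar (`dlon * dlat` in
#' squared degrees / axis units) for use on abstract planar data.
#'
#' Kernel smoothing inflates the spread of the estimated surface: its
#' variance per axis is `sigma^2 + h^2`, so the area of a fixed-mass
#' isopleth is inflated by a factor of about `1 + h^2/sigma^2`
#' (`1 + n_eff^(-1/3)` under the Scott rule).  With
#' `variance_correction = TRUE` (the default) the kernel centers are
#' contracted toward the weighted centroid by `sqrt(1 - h_j^2/sigma_j^2)`
#' per axis, so the surface's variance matches the weighted sample's and
#' fixed-mass isopleth areas are unbiased to first order for elliptical
#' data.  Set it to `FALSE` for the plain (uncorrected) weighted KDE.
#'
#' @param lon,lat point coordinates; `w` nonnegative weights, positive sum.
#' @param bandwidth `"scott"` or a numeric length-2 `(h_lon, h_lat)`.
#' @param grid_n cells per axis.
#' @param pad grid padding beyond the data extent, in bandwidths.
#' @param cell_area `"geodesic"` (km^2) or `"planar"`.
#' @param variance_correction contract kernel centers so the surface
#'   variance equals the sample variance (default `TRUE`).
#' @return a `density_surface`: `lon`, `lat` (cell centers), `mass`
#'   (lon x lat matrix, sums to 1), `dens`, `area` (cell areas), `h`
#'   (bandwidths used).
#' @export
weighted_kde <- function(lon, lat, w, bandwidth = "scott", grid_n = 200,
                         pad = 3, cell_area = c("geodesic", "planar"),
                         variance_correction = TRUE) {
  cell_area <- match.arg(cell_area)
  stopifnot(length(lon) == length(lat), length(lon) == length(w))
  keep <- w > 0
  if (any(w < 0)) stop("weights must be nonnegative")
  if (!any(keep)) stop("density undefined: all weights are zero")
  lon <- lon[keep]; lat <- lat[keep]; w <- w[keep]
  if (identical(bandwidth, "scott")) {
    n_eff <- sum(w)^2 / sum(w^2)
    h <- c(wsd(lon, w), wsd(lat, w)) * n_eff^(-1 / 6)
  } else {
    h <- as.numeric(bandwidth)
    stopifnot(length(h) == 2)
  }
  if (any(h <= 0)) {
    stop("degenerate surface: zero bandwidth (single unique point?)")
  }
  gx <- seq(min(lon) - pad * h[1], max(lon) + pad * h[1], length.out = grid_n)
  gy <- seq(min(lat) - pad * h[2], max(lat) + pad * h[2], length.out = grid_n)
  if (variance_correction) {
    sig <- c(wsd(lon, w), wsd(lat, w))
    a <- sqrt(pmax(0, 1 - (h / sig)^2))
    a[!is.finite(a)] <- 0
    mx <- sum(w * lon) / sum(w)
    my <- sum(w * lat) / sum(w)
    lon <- mx + a[1] * (lon - mx)
    lat <- my + a[2] * (lat - my)
  }
  ## dens[i, j] = sum_k w_k phi((gx_i - lon_k)/h1) phi((gy_j - lat_k)/h2)
  Ax <- stats::dnorm(outer(gx, lon, "-") / h[1]) / h[1]
  Ay <- stats::dnorm(outer(gy, lat, "-") / h[2]) / h[2]
  dens <- Ax %*% (w * t(Ay))
  dx <- gx[2] - gx[1]
  dy <- gy[2] - gy[1]
  mass <- dens * dx * dy
  mass <- mass / sum(mass)
  area <- if (cell_area == "geodesic") {
    matrix(KM_PER_DEG_LAT^2 * dx * dy * rep(cos(gy * pi / 180), each = grid_n),
           grid_n, grid_n)
  } else {
    matrix(dx * dy, grid_n, grid_n)
  }
  structure(list(lon = gx, lat = gy, mass = mass, dens = dens, area = area,
                 h = h), class = "density_surface")
}

#' Smallest region holding a given fraction of the density mass
#'
#' Cells are ranked by density (descending, stable order) and accumulated
#' until the cumulative mass first reaches the level; the region is the set
#' of accumulated cells.  Cells of equal density beyond the cut are *not*
#' pulled in (stable-sort convention), so a uniform surface of 100 cells at
#' level 0.95 yields 95 cells.
#'
#' @param surface a `density_surface`.
#' @param level cumulative-mass level in (0, 1); default 0.95.
#' @return list with `mask` (logical lon x lat matrix), `area` (sum of
#'   selected cell areas), `level`.
#' @export
isopleth <- function(surface, level = 0.95) {
  stopifnot(inherits(surface, "density_surface"))
  if (!is.finite(level) || level <= 0 || level >= 1) {
    stop("level must be in (0, 1)")
  }
  ord <- order(surface$mass, decreasing = TRUE)
  k <- which(cumsum(surface$mass[ord]) >= level)[1]
  mask <- matrix(FALSE, nrow(surface$mass), ncol(surface$mass))
  mask[ord[seq_len(k)]] <- TRUE
  list(mask = mask, area = sum(surface$area[mask]), level = level)
}

#' Southern and northern extent of an isopleth region
#'
#' @param surface the `density_surface` the mask belongs to.
#' @param mask logical matrix from [isopleth()].
#' @return named vector `c(south, north)` of cell-center latitudes.
#' @export
range_extent <- function(surface, mask) {
  if (!any(mask)) stop("empty region")
  lat_in <- surface$lat[apply(mask, 2, any)]
  c(south = min(lat_in), north = max(lat_in))
}

period_rows <- function(records, period) {
  records$year >= period[1] & records$year <= period[2]
}

#' Distribution-shift metrics for one species and season
#'
#' For each period: the CPUE-weighted centroid, the CPUE-weighted Gaussian
#' KDE, its 95% (by default) kernel-density range area and the range-edge
#' latitudes.  The centroid shift is the great-circle distance between the
#' two period centroids; the area change is
#' `100 * (area2 - area1) / area1`.
#'
#' @param records hauls of a single species and season (long-format rows
#'   with `year`, `lat`, `lon`, `cpue`).
#' @param periods a [period_spec()].
#' @param level isopleth level for the range area.
#' @param bandwidth,grid_n passed to [weighted_kde()].
#' @return one-row data.frame (`RangeMetrics`); all metric columns are `NA`
#'   with a `reason` when either period has zero total CPUE.
#' @export
compute_range_metrics <- function(records, periods = period_spec(),
                                  level = 0.95, bandwidth = "scott",
                                  grid_n = 200) {
  stopifnot(inherits(periods, "period_spec"))
  out <- data.frame(centroid1_lat = NA_real_, centroid1_lon = NA_real_,
                    centroid2_lat = NA_real_, centroid2_lon = NA_real_,
                    shift_km = NA_real_, area1_km2 = NA_real_,
                    area2_km2 = NA_real_, pct_area_change = NA_real_,
                    south1 = NA_real_, north1 = NA_real_,
                    south2 = NA_real_, north2 = NA_real_,
                    d_north = NA_real_, d_south = NA_real_,
                    n1 = NA_integer_, n2 = NA_integer_,
                    reason = NA_character_)
  per <- list(records[period_rows(records, periods$period1), , drop = FALSE],
              records[period_rows(records, periods$period2), , drop = FALSE])
  tot <- vapply(per, function(d) sum(d$cpue), 0)
  if (any(tot <= 0)) {
    out$reason <- paste0("zero total CPUE in period ", which(tot <= 0)[1])
    return(out)
  }
  cent <- lapply(per, function(d) weighted_centroid(d$lat, d$lon, d$cpue))
  surf <- lapply(per, function(d) weighted_kde(d$lon, d$lat, d$cpue,
                                               bandwidth = bandwidth,
                                               grid_n = grid_n))
  iso <- lapply(surf, isopleth, level = level)
  ext <- mapply(function(s, i) range_extent(s, i$mask), surf, iso,
                SIMPLIFY = FALSE)
  out$centroid1_lat <- cent[[1]]["lat"]; out$centroid1_lon <- cent[[1]]["lon"]
  out$centroid2_lat <- cent[[2]]["lat"]; out$centroid2_lon <- cent[[2]]["lon"]
  out$shift_km <- geodesic_km(cent[[1]]["lat"], cent[[1]]["lon"],
                              cent[[2]]["lat"], cent[[2]]["lon"])
  out$area1_km2 <- iso[[1]]$area
  out$area2_km2 <- iso[[2]]$area
  out$pct_area_change <- 100 * (iso[[2]]$area - iso[[1]]$area) / iso[[1]]$area
  out$south1 <- ext[[1]]["south"]; out$north1 <- ext[[1]]["north"]
  out$south2 <- ext[[2]]["south"]; out$north2 <- ext[[2]]["north"]
  out$d_north <- out$north2 - out$north1
  out$d_south <- out$south2 - out$south1
  out$n1 <- nrow(per[[1]]); out$n2 <- nrow(per[[2]])
  out
}

#' Range metrics for every retained species and season
#'
#' @param records long-format survey rows (multiple species/seasons).
#' @param species optional species subset; default all present.
#' @param seasons optional season subset; default all present.
#' @inheritParams compute_range_metrics
#' @return data.frame with one row per species x season.
#' @export
range_metrics_table <- function(records, species = NULL, seasons = NULL,
                                periods = period_spec(), level = 0.95,
                                bandwidth = "scott", grid_n = 200) {
  species <- species %||% sort(unique(records$species))
  seasons <- seasons %||% sort(unique(records$season))
  rows <- list()
  for (se in seasons) {
    for (sp in species) {
      d <- records[records$species == sp & records$season == se, ,
                   drop = FALSE]
      m <- compute_range_metrics(d, periods = periods, level = level,
                                 bandwidth = bandwidth, grid_n = grid_n)
      rows[[length(rows) + 1]] <- cbind(data.frame(species = sp, season = se),
                                        m)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
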