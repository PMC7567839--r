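## Survey ingestion: typed reading of the long-format haul table, a
## nearest-neighbour substrate join, and the strata/species inclusion
## filters applied before any modeling.

SURVEY_COLUMNS <- c("haul_id", "year", "season", "stratum", "lat", "lon",
                    "depth", "btemp", "bsalin", "grainsize", "species",
                    "cpue")

#' Filtering rules for strata and species retention
#'
#' Species are retained when present (CPUE > 0 in at least one haul) in at
#' least `floor(min_presence_fraction * n_years)` years in each season —
#' 16 of 33 years under the defaults — and when their summed CPUE strictly
#' exceeds `edge_cpue_min` within both the first and the last
#' `edge_period_years` years, again in each season.
#'
#' @param year_min,year_max inclusive year span (defaults 1986 and 2018).
#' @param min_presence_fraction fraction of years a species must be present
#'   in each season (default 0.5).
#' @param edge_period_years length of the first/last window (default 5).
#' @param edge_cpue_min summed-CPUE threshold for the edge windows, strict
#'   inequality (default 20).
#' @return a `filter_rules` list.
#' @export
filter_rules <- function(year_min = 1986L, year_max = 2018L,
                         min_presence_fraction = 0.5,
                         edge_period_years = 5L, edge_cpue_min = 20) {
  if (year_min >= year_max) stop("year_min must be < year_max")
  if (min_presence_fraction <= 0 || min_presence_fraction > 1) {
    stop("min_presence_fraction must be in (0, 1]")
  }
  if (edge_period_years < 1) stop("edge_period_years must be >= 1")
  structure(list(year_min = as.integer(year_min),
                 year_max = as.integer(year_max),
                 min_presence_fraction = min_presence_fraction,
                 edge_period_years = as.integer(edge_period_years),
                 edge_cpue_min = edge_cpue_min),
            class = "filter_rules")
}

#' Read a long-format survey table
#'
#' Rows with unparseable or out-of-range coordinates, missing years or
#' negative CPUE are rejected; the rejected count is reported via
#' `message()`.
#'
#' @param path CSV file with the columns `haul_id, year, season, stratum,
#'   lat, lon, depth, btemp, bsalin, grainsize, species, cpue`.
#' @return data.frame of typed haul records.
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SURVEY_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("survey file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[SURVEY_COLUMNS]
  if (!nrow(df)) {
    warning("survey file contains a header but no rows")
    return(df)
  }
  for (cl in c("year", "lat", "lon", "depth", "btemp", "bsalin",
               "grainsize", "cpue")) {
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  }
  df$year <- as.integer(df$year)
  bad <- !is.finite(df$lat) | !is.finite(df$lon) |
    abs(df$lat) > 90 | abs(df$lon) > 180 |
    is.na(df$year) | !is.finite(df$cpue) | df$cpue < 0
  if (any(bad)) {
    message("read_survey: rejected ", sum(bad),
            " row(s) with invalid coordinates, year or CPUE")
    df <- df[!bad, , drop = FALSE]
  }
  if (anyDuplicated(df[c("haul_id", "species")])) {
    stop("duplicate (haul_id, species) rows in survey file")
  }
  rownames(df) <- NULL
  df
}

#' Write a survey table
#'
#' @param records data.frame of haul records.
#' @param path output CSV path.
#' @export
write_survey <- function(records, path) {
  utils::write.csv(records[intersect(SURVEY_COLUMNS, names(records))],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a substrate point table
#'
#' @param path CSV with columns `lon`, `lat`, `grainsize_mm`.
#' @return data.frame.
#' @export
read_substrate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lon", "lat", "grainsize_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("substrate file is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

#' Fill grain size by nearest substrate point
#'
#' Each haul takes the grain size of its great-circle nearest substrate
#' point; on an exact distance tie the lower-index donor wins (stable
#' `which.min`).  Hauls farther than `max_km` from every donor get a
#' missing grain size.  The donor distance is recorded in
#' `grainsize_donor_km`.
#'
#' @param records haul records.
#' @param substrate data.frame with `lon`, `lat`, `grainsize_mm`.
#' @param max_km maximum donor distance in km (default 50).
#' @return `records` with `grainsize` and `grainsize_donor_km` filled.
#' @export
join_substrate <- function(records, substrate, max_km = 50) {
  if (!nrow(substrate)) stop("substrate table is empty")
  pos <- unique(records[c("lat", "lon")])
  idx <- integer(nrow(pos))
  dkm <- numeric(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    d <- geodesic_km(pos$lat[i], pos$lon[i], substrate$lat, substrate$lon)
    idx[i] <- which.min(d)
    dkm[i] <- d[idx[i]]
  }
  key <- paste(records$lat, records$lon)
  m <- match(key, paste(pos$lat, pos$lon))
  g <- substrate$grainsize_mm[idx][m]
  d <- dkm[m]
  g[d > max_km] <- NA_real_
  records$grainsize <- g
  records$grainsize_donor_km <- d
  records
}

#' Keep only strata sampled in every year and season
#'
#' A stratum survives only if it has at least one haul in every (year,
#' season) cell of `[year_min, year_max]` x seasons; seasons are those
#' present in the data.  Records outside the year span are dropped first.
#'
#' @param records haul records.
#' @param rules a [filter_rules()].
#' @return records restricted to consistently sampled strata.
#' @export
filter_strata <- function(records, rules = filter_rules()) {
  stopifnot(inherits(rules, "filter_rules"))
  records <- records[records$year >= rules$year_min &
                       records$year <= rules$year_max, , drop = FALSE]
  if (!nrow(records)) stop("no records within the year span")
  years <- rules$year_min:rules$year_max
  seasons <- unique(records$season)
  hauls <- unique(records[c("stratum", "year", "season")])
  cells <- table(factor(hauls$stratum),
                 factor(hauls$year, levels = years),
                 factor(hauls$season, levels = seasons))
  full <- apply(cells > 0, 1, all)
  keep <- names(full)[full]
  dropped <- setdiff(unique(records$stratum), keep)
  if (length(dropped)) {
    message("filter_strata: dropped ", length(dropped), " stratum/strata (",
            paste(dropped, collapse = ", "), ")")
  }
  if (!length(keep)) stop("no stratum is sampled in every year and season")
  out <- records[records$stratum %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the species retention rules
#'
#' @param records haul records (strata filter already applied).
#' @param rules a [filter_rules()].
#' @return list with `retained` (character vector) and `log` (data.frame
#'   with per-species decisions and reasons).
#' @export
filter_species <- function(records, rules = filter_rules()) {
  stopifnot(inherits(rules, "filter_rules"))
  n_years <- rules$year_max - rules$year_min + 1L
  ## "at least half of 33 years" means 16 in the source survey, so the
  ## generalized threshold is the floor of fraction * n_years (>= 1)
  need_years <- max(1L, floor(rules$min_presence_fraction * n_years))
  first_w <- rules$year_min + seq_len(rules$edge_period_years) - 1L
  last_w <- rules$year_max - rules$edge_period_years + seq_len(rules$edge_period_years)
  seasons <- unique(records$season)
  species <- sort(unique(records$species))
  log <- data.frame(species = species, retained = NA,
                    reason = NA_character_)
  for (k in seq_along(species)) {
    d <- records[records$species == species[k], , drop = FALSE]
    reasons <- character()
    for (se in seasons) {
      ds <- d[d$season == se, , drop = FALSE]
      pres_years <- length(unique(ds$year[ds$cpue > 0]))
      if (pres_years < need_years) {
        reasons <- c(reasons, sprintf("presence (%s: %d/%d years)", se,
                                      pres_years, need_years))
      }
      e1 <- sum(ds$cpue[ds$year %in% first_w])
      e2 <- sum(ds$cpue[ds$year %in% last_w])
      if (!(e1 > rules$edge_cpue_min)) {
        reasons <- c(reasons, sprintf("edge CPUE (%s, first window: %g)",
                                      se, e1))
      }
      if (!(e2 > rules$edge_cpue_min)) {
        reasons <- c(reasons, sprintf("edge CPUE (%s, last window: %g)",
                                      se, e2))
      }
    }
    log$retained[k] <- !length(reasons)
    log$reason[k] <- if (length(reasons)) paste(reasons, collapse = "; ") else "retained"
  }
  list(retained = species[log$retained], log = log)
}
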