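test_that("read_survey types, rejects and round-trips records", {
  sim <- build_survey(fixture_config(seed = 4))
  f <- withr::local_tempfile(fileext = ".csv")
  write_survey(sim$survey, f)
  back <- read_survey(f)
  expect_equal(nrow(back), nrow(sim$survey))
  expect_equal(back$cpue, sim$survey$cpue)
  expect_equal(back$lat, sim$survey$lat, tolerance = 1e-12)

  ## rejection of malformed rows, with a reported count
  bad <- sim$survey[1:3, ]
  bad$cpue[1] <- -1
  bad$lat[2] <- 95
  write_survey(bad, f)
  expect_message(got <- read_survey(f), "rejected 2")
  expect_equal(nrow(got), 1)

  ## empty file with header
  write_survey(sim$survey[0, ], f)
  expect_warning(empty <- read_survey(f), "no rows")
  expect_equal(nrow(empty), 0)

  ## missing column named in the error
  df <- sim$survey[1:2, setdiff(names(sim$survey), "bsalin")]
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_survey(f), "bsalin")
})

test_that("substrate join takes the nearest donor with tie-break and cutoff", {
  rec <- toy_survey(list(list(lat = 40, lon = -70),
                         list(lat = 40.5, lon = -70),
                         list(lat = 44, lon = -60)))
  sub <- data.frame(lon = c(-70, -70), lat = c(40, 41),
                    grainsize_mm = c(1.5, 0.3))
  out <- join_substrate(rec, sub, max_km = 100)
  expect_equal(out$grainsize[1], 1.5)  # exact match, zero distance
  expect_equal(out$grainsize_donor_km[1], 0)
  expect_equal(out$grainsize[2], 1.5)  # equidistant: lower index wins
  expect_true(is.na(out$grainsize[3]))  # beyond cutoff
  expect_error(join_substrate(rec, sub[0, ]), "empty")
})

test_that("strata must be sampled in every year and season to survive", {
  rows <- list()
  for (y in 2000:2002) for (se in c("spring", "fall")) {
    rows <- c(rows, list(list(year = y, season = se, stratum = "full")))
    if (!(y == 2001 && se == "fall")) {
      rows <- c(rows, list(list(year = y, season = se, stratum = "gappy")))
    }
  }
  rec <- toy_survey(rows)
  rules <- filter_rules(year_min = 2000, year_max = 2002)
  expect_message(kept <- filter_strata(rec, rules), "gappy")
  expect_equal(unique(kept$stratum), "full")
  ## idempotent
  expect_equal(filter_strata(kept, rules), kept)
  ## simulated surveys guarantee full coverage
  sim <- build_survey(fixture_config(seed = 6))
  rules2 <- filter_rules(year_min = 2011, year_max = 2018)
  expect_equal(sort(unique(filter_strata(sim$survey, rules2)$stratum)),
               sort(unique(sim$survey$stratum)))
})

test_that("species retention follows the presence and edge-window rules", {
  ## presence hauls sit outside the 1986-1990 / 2014-2018 edge windows so
  ## each window's summed CPUE is exactly the edge haul's value
  mk_species <- function(name, mid_years, edge1, edge2) {
    rows <- list()
    for (se in c("spring", "fall")) {
      for (y in mid_years) {
        rows <- c(rows, list(list(year = y, season = se, species = name,
                                  cpue = 1)))
      }
      rows <- c(rows, list(list(year = 1986L, season = se, species = name,
                                cpue = edge1),
                           list(year = 2018L, season = se, species = name,
                                cpue = edge2)))
    }
    rows
  }
  rec <- toy_survey(c(
    mk_species("keeper", 1991:2004, 25, 30),   # 14 + 2 = 16 years, edges pass
    mk_species("sparse", 1991:2003, 25, 30),   # 13 + 2 = 15 years -> drop
    mk_species("edge20", 1991:2006, 20, 30),   # first-window sum exactly 20
    mk_species("edge21", 1991:2006, 20.5, 30)))  # strictly above 20
  res <- filter_species(rec, filter_rules())
  expect_setequal(res$retained, c("keeper", "edge21"))
  expect_match(res$log$reason[res$log$species == "sparse"], "presence")
  expect_match(res$log$reason[res$log$species == "edge20"], "edge CPUE")

  ## monotone in the edge threshold: raising it never adds species
  for (thr in c(0, 5, 20, 25, 40)) {
    r1 <- filter_species(rec, filter_rules(edge_cpue_min = thr))$retained
    r2 <- filter_species(rec, filter_rules(edge_cpue_min = thr + 5))$retained
    expect_true(all(r2 %in% r1))
  }
})

test_that("rule constructors validate their arguments", {
  expect_error(filter_rules(year_min = 2018, year_max = 1986), "year_min")
  expect_error(filter_rules(min_presence_fraction = 0), "presence")
  expect_error(filter_rules(edge_period_years = 0), "edge_period_years")
})
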