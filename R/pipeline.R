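## End-to-end orchestration: simulate (or read) -> filter -> importance ->
## range metrics -> comparisons, with persisted stage outputs and a
## reproducibility manifest.

#' Configure an end-to-end run
#'
#' Exactly one input mode must be set: `simulate` (a
#' [simulation_config()]) or `survey_file` (a CSV in the survey schema;
#' optionally with `substrate_file` for the grain-size join and
#' `species_file` mapping species to life history).  In simulate mode the
#' life-history map comes from the generator's truth table.
#'
#' @param simulate a [simulation_config()], or `NULL`.
#' @param survey_file,substrate_file,species_file input CSV paths, or `NULL`.
#' @param rules a [filter_rules()].
#' @param fit_spec a [smooth_fit_spec()].
#' @param periods a [period_spec()].
#' @param kde_grid_n,kde_bandwidth,isopleth_level KDE options.
#' @param adjust multiple-testing mode for [pairwise_compare()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, survey_file = NULL,
                            substrate_file = NULL, species_file = NULL,
                            rules = filter_rules(),
                            fit_spec = smooth_fit_spec(),
                            periods = period_spec(),
                            kde_grid_n = 200, kde_bandwidth = "scott",
                            isopleth_level = 0.95,
                            adjust = "none") {
  problems <- character()
  if (is.null(simulate) == is.null(survey_file)) {
    problems <- c(problems,
                  "exactly one of 'simulate' and 'survey_file' must be set")
  }
  if (!is.null(simulate) && !inherits(simulate, "simulation_config")) {
    problems <- c(problems, "'simulate' must be a simulation_config")
  }
  if (!inherits(rules, "filter_rules")) {
    problems <- c(problems, "'rules' must be a filter_rules")
  }
  if (!inherits(fit_spec, "smooth_fit_spec")) {
    problems <- c(problems, "'fit_spec' must be a smooth_fit_spec")
  }
  if (!inherits(periods, "period_spec")) {
    problems <- c(problems, "'periods' must be a period_spec")
  }
  if (length(problems)) {
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(list(simulate = simulate, survey_file = survey_file,
                 substrate_file = substrate_file,
                 species_file = species_file, rules = rules,
                 fit_spec = fit_spec, periods = periods,
                 kde_grid_n = kde_grid_n, kde_bandwidth = kde_bandwidth,
                 isopleth_level = isopleth_level, adjust = adjust),
            class = "pipeline_config")
}

config_digest <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::serializeJSON(config, pretty = FALSE), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis
#'
#' Stages run in order (simulate/read, substrate join if configured,
#' strata and species filters, deviance table, range metrics,
#' comparisons); each stage's table is written under `out_dir` as CSV
#' before the next stage starts, so a failure preserves prior outputs.  A
#' `manifest.json` records the configuration hash, seed, package version
#' and the md5 checksum of every written file, and `summary.txt` tabulates
#' species counts per life history and strongest predictor and the
#' comparison results.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with every stage's in-memory result.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  stage <- "simulate/read"
  res <- tryCatch({
    if (!is.null(config$simulate)) {
      sim <- build_survey(config$simulate, truth_periods = config$periods)
      survey <- sim$survey
      life <- sim$truth[c("species", "life_history")]
      emit(survey, "survey.csv")
      emit(sim$truth, "truth.csv")
    } else {
      survey <- read_survey(config$survey_file)
      if (!is.null(config$substrate_file)) {
        stage <- "substrate join"
        survey <- join_substrate(survey,
                                 read_substrate(config$substrate_file))
      }
      life <- if (!is.null(config$species_file)) {
        utils::read.csv(config$species_file, stringsAsFactors = FALSE)
      } else {
        data.frame(species = unique(survey$species),
                   life_history = NA_character_)
      }
    }

    stage <- "filters"
    filtered <- filter_strata(survey, config$rules)
    fs <- filter_species(filtered, config$rules)
    filtered <- filtered[filtered$species %in% fs$retained, , drop = FALSE]
    emit(fs$log, "species_filter_log.csv")
    emit(filtered, "survey_filtered.csv")

    stage <- "importance"
    dev <- deviance_table(filtered, spec = config$fit_spec)
    emit(dev$table, "deviance_table.csv")
    emit(dev$strongest, "strongest_predictor.csv")

    stage <- "range metrics"
    metrics <- range_metrics_table(filtered, periods = config$periods,
                                   level = config$isopleth_level,
                                   bandwidth = config$kde_bandwidth,
                                   grid_n = config$kde_grid_n)
    emit(metrics, "range_metrics.csv")

    stage <- "comparisons"
    cmp <- compare_all(metrics, dev$strongest, life, adjust = config$adjust)
    emit(cmp$comparisons, "comparisons.csv")
    emit(cmp$summaries, "group_summaries.csv")

    list(survey = survey, filtered = filtered, species_log = fs$log,
         deviance = dev, metrics = metrics, comparisons = cmp, life = life)
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  summary_path <- file.path(out_dir, "summary.txt")
  writeLines(pipeline_summary(res), summary_path)
  written <- c(written, summary_path)

  manifest <- list(
    config_md5 = config_digest(config),
    seed = if (!is.null(config$simulate)) config$simulate$seed else NA,
    package_version = as.character(utils::packageVersion("fishshift")),
    files = as.list(stats::setNames(unname(tools::md5sum(written)),
                                    basename(written))),
    created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

pipeline_summary <- function(res) {
  lines <- c("fishshift pipeline summary", "==========================", "")
  for (se in sort(unique(res$deviance$strongest$season))) {
    st <- res$deviance$strongest[res$deviance$strongest$season == se, ]
    st$life_history <- res$life$life_history[match(st$species,
                                                   res$life$species)]
    lines <- c(lines, sprintf("Season: %s", se),
               sprintf("  species retained: %d", nrow(st)), "")
    tab <- table(st$life_history, st$strongest_predictor)
    lines <- c(lines, "  strongest predictor by life history:",
               utils::capture.output(print(tab)), "")
  }
  lines <- c(lines, "Pairwise comparisons (two-sided rank-sum):",
             utils::capture.output(print(res$comparisons$comparisons,
                                         row.names = FALSE)))
  lines
}

#' Write miniature fixture datasets
#'
#' A small synthetic survey (2 strata, 3 species covering every life
#' history, 8 years, both seasons; under 500 haul-species rows) plus a
#' matching substrate table and species metadata table, sized to flow
#' through every pipeline stage in seconds.
#'
#' @param out_dir writable directory.
#' @param seed integer seed.
#' @return (invisibly) named vector of file paths.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- fixture_config(seed)
  sim <- build_survey(cfg, truth_periods = period_spec(c(2011, 2012),
                                                       c(2017, 2018)))
  survey_path <- file.path(out_dir, "survey.csv")
  write_survey(sim$survey, survey_path)
  ## substrate point table sampled from the simulated grain field
  env <- sim$env
  ij <- expand.grid(i = seq(1, length(env$lon), by = 2),
                    j = seq(1, length(env$lat), by = 2))
  substrate <- data.frame(lon = env$lon[ij$i], lat = env$lat[ij$j],
                          grainsize_mm = env$grain[as.matrix(ij)])
  substrate_path <- file.path(out_dir, "substrate.csv")
  utils::write.csv(substrate, substrate_path, row.names = FALSE)
  species_path <- file.path(out_dir, "species.csv")
  utils::write.csv(sim$truth[c("species", "life_history")], species_path,
                   row.names = FALSE)
  invisible(c(survey = survey_path, substrate = substrate_path,
              species = species_path))
}

#' Small simulation configuration used for fixtures and fast tests
#'
#' @param seed integer seed.
#' @param n_years span (default 8, years 2011-2018).
#' @return a [simulation_config()].
#' @export
fixture_config <- function(seed = 1L, n_years = 8L) {
  strata <- list(
    stratum_spec("A", c(36, 40), c(-75, -70), area_km2 = 2500),
    stratum_spec("B", c(40, 44), c(-75, -70), area_km2 = 2500))
  species <- list(
    species_profile("pelagic_f", "pelagic", 1.6,
                    niche = list(btemp = list(opt = NA, breadth = 2.2,
                                              weight = 4)),
                    anchor_lat = 39, shift_km_per_decade = 70),
    species_profile("demersal_f", "demersal", 1.8,
                    niche = list(btemp = list(opt = NA, breadth = 2.5,
                                              weight = 1.8),
                                 grainsize = list(opt = 1.2, breadth = 0.5,
                                                  weight = 1.8)),
                    anchor_lat = 40, shift_km_per_decade = 30),
    species_profile("benthic_f", "benthic", 1.8,
                    niche = list(grainsize = list(opt = 2.0, breadth = 0.6,
                                                  weight = 3))))
  simulation_config(seed = seed, n_years = n_years, year_min = 2019L - n_years,
                    strata = strata, stations_per_unit_area = 2e-3,
                    species = species, grid_res = 0.25)
}
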