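#!/usr/bin/env Rscript
# Stage 2: apply the survey inclusion filters.
#
# Strata must be sampled in every year and season of 1986-2018; species must
# be present in at least 16 of the 33 years in each season and show summed
# CPUE > 20 in both the 1986-1990 and 2014-2018 windows in each season.

library(fishshift)

survey <- read_survey("results/survey.csv")
rules <- filter_rules()

filtered <- filter_strata(survey, rules)
fs <- filter_species(filtered, rules)
filtered <- filtered[filtered$species %in% fs$retained, ]

write_survey(filtered, "results/survey_filtered.csv")
write.csv(fs$log, "results/species_filter_log.csv", row.names = FALSE)

message(sprintf("strata kept: %d; species retained: %d of %d",
                length(unique(filtered$stratum)), length(fs$retained),
                length(unique(survey$species))))
dropped <- fs$log[!fs$log$retained, ]
if (nrow(dropped)) print(dropped, row.names = FALSE) else
  message("no species dropped under the default scenario")
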