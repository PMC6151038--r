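#!/usr/bin/env Rscript
# Stage 1 — simulate the survey.
#
# Draws the default synthetic panel: four equal smoking-status strata of
# 410 respondents, each randomized to the personal or general risk
# framing, assessing up to five objects (never smokers under the personal
# framing skip NRT and Cessation) in randomized sequences; 18 health-risk
# and 7 addiction-risk items on a 1-5 scale with ~12% "don't know";
# auxiliary VAS measures with reliability 0.6. Writes the long CSV, the
# generating truth, and a per-item missing/don't-know summary.

suppressPackageStartupMessages(library(raschval))
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(seed = 20140201)
sim <- generate_survey(cfg)

write_responses(sim$data, "results/survey_long.csv")
readr::write_csv(sim$truth$items, "results/truth_items.csv")
readr::write_csv(sim$truth$persons, "results/truth_persons.csv")
readr::write_csv(sim$truth$vas, "results/truth_vas.csv")

for (s in c("health", "addiction")) {
  am <- to_analysis_matrix(sim$data, s)
  ms <- missing_summary(am)
  readr::write_csv(ms, sprintf("results/%s_missing_summary.csv", s))
  cat(sprintf("%s: %d rows x %d items; dk%% %.1f-%.1f, flagged items: %d\n",
              s, nrow(am$scores), ncol(am$scores),
              min(ms$dk_pct), max(ms$dk_pct), sum(ms$flag_missing)))
}
cat("respondents:", length(unique(sim$data$respondent_id)), "\n")
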