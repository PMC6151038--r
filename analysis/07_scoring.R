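#!/usr/bin/env Rscript
# Stage 7 — raw-score to measure conversion tables.
#
# For each scale's full administered form, solves the WLE score equation
# at every raw score (finite at the extremes via the Warm correction) and
# maps the logit measures to the 0-100 reporting metric: 50 at the
# calibration mean, the extreme measures at/inside 0 and 100.

suppressPackageStartupMessages(library(raschval))

sim <- generate_survey(generator_config(seed = 20140201))

for (s in c("health", "addiction")) {
  am <- to_analysis_matrix(sim$data, s)
  fit <- calibrate_items(am)
  items <- applicable_items(pri_item_bank(), s, "CC")
  conv <- build_conversion_table(fit$tau[items$item_id, , drop = FALSE])
  write_conversion_table(conv, sprintf("results/%s_conversion.csv", s))
  cat(sprintf("%s: raw 0..%d -> logits [%.2f, %.2f]; logit 0 -> %.1f; symmetric: %s\n",
              s, max(conv$raw_score), min(conv$logit), max(conv$logit),
              logit_to_0_100(0, conv), attr(conv, "symmetric")))
}
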