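#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Generates the default synthetic cohort: 72 participants, each walking the
# 40 m out-and-back obstacle course once per haptic x audio condition cell
# (order randomized per participant), telemetry at 72 Hz, plus questionnaire
# answers. Extracts the six per-trial movement metrics and writes the tables
# that the later steps consume. Raw trial logs stay in memory by default
# (they are ~100 MB on disk); set WRITE_LOGS <- TRUE to archive them.

library(navkin)

WRITE_LOGS <- FALSE
out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- cohort_config(n_participants = 72, seed = 1)
message("generating cohort: ", cfg$n_participants, " participants x 4 cells")
cohort <- generate_cohort(cfg)
message(length(cohort$trials), " trials simulated")

if (WRITE_LOGS) write_cohort(cohort, file.path(out, "cohort"))
write_manifest(cohort$manifest, file.path(out, "manifest.csv"))
write_questionnaire(cohort$questionnaire, file.path(out, "questionnaire.csv"))

metrics <- compute_metrics_table(cohort)
write_metrics_table(metrics, file.path(out, "metrics.csv"))
message("metrics table: ", nrow(metrics), " rows -> results/metrics.csv")

cm <- condition_summaries(metrics)
for (m in unique(cm$metric)) {
  rows <- cm[cm$metric == m, ]
  message(sprintf("  %-16s cell means: %s", m,
                  paste(round(rows$mean, 2), collapse = "  ")))
}
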