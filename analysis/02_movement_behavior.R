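#!/usr/bin/env Rscript
# Step 2 — condition-cell summaries and interaction-plot data.
#
# Reads the per-trial metrics from step 1 and exports, per metric, the 2x2
# cell means with standard errors (the data behind factorial interaction
# plots), plus rendered figures.

library(navkin)

metrics <- read_metrics_table("results/metrics.csv")
summaries <- condition_summaries(metrics)
readr::write_csv(summaries, "results/condition_summaries.csv")

plot_data <- export_interaction_plot_data(summaries)
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
for (m in names(plot_data)) {
  readr::write_csv(plot_data[[m]], sprintf("results/interaction_%s.csv", m))
  ggplot2::ggsave(sprintf("results/figures/interaction_%s.png", m),
                  plot_interaction(summaries, m),
                  width = 4.5, height = 3.5, dpi = 150)
}
message("wrote ", length(plot_data), " interaction tables and figures")

# quick readout of the headline contrasts
h <- function(m, on) mean(metrics[[m]][metrics$haptic == on])
a <- function(m, on) mean(metrics[[m]][metrics$audio == on])
message(sprintf("collisions: haptic on %.2f vs off %.2f",
                h("n_collisions", TRUE), h("n_collisions", FALSE)))
message(sprintf("SPARC: audio on %.2f vs off %.2f",
                a("SPARC", TRUE), a("SPARC", FALSE)))
message(sprintf("completion time: haptic on %.1f s vs off %.1f s",
                h("completion_time", TRUE), h("completion_time", FALSE)))
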