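#!/usr/bin/env Rscript
# Step 3 — outlier screening and factorial inference.
#
# Screens each metric with the per-cell 1.5 IQR rule, then runs the two-way
# repeated-measures mixed ANOVA (completion time, trajectory length,
# rank-transformed SPARC, both entropies) and the Scheirer-Ray-Hare rank test
# (collision counts), and writes the effect tables.

library(navkin)

metrics <- read_metrics_table("results/metrics.csv")
analysis <- analyze_metrics(metrics)

readr::write_csv(analysis$effects, "results/effects.csv")
readr::write_csv(analysis$outliers, "results/outliers.csv")

message("outliers removed per metric:")
for (i in seq_len(nrow(analysis$outliers))) {
  message(sprintf("  %-16s %d/%d (%.1f%%)", analysis$outliers$metric[i],
                  analysis$outliers$count[i], analysis$n_input,
                  analysis$outliers$percentage[i]))
}
message("effect tests (statistic [df], p):")
e <- analysis$effects
for (i in seq_len(nrow(e))) {
  message(sprintf("  %-16s %-11s %s = %8.4f  p = %.4f", e$metric[i],
                  e$effect[i], e$statistic_kind[i], e$statistic[i],
                  e$p_value[i]))
}
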