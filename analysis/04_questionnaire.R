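#!/usr/bin/env Rscript
# Step 4 — questionnaire descriptives.
#
# Summarizes the generated cohort's questionnaire (counts, fractions, integer
# percentages per category) and, for reference, the published category
# tallies of the original 72-participant study.

library(navkin)

q <- read_questionnaire("results/questionnaire.csv")
s <- summarize_questionnaire(q)
readr::write_csv(s, "results/questionnaire_summary.csv")
message("generated cohort, preferred condition:")
pref <- s[s$item == "q6_preferred_condition", ]
for (i in seq_len(nrow(pref))) {
  message(sprintf("  %-7s %2d/%d (%d%%)", pref$category[i], pref$count[i],
                  pref$denominator[i], pref$percentage[i]))
}

published <- questionnaire_from_counts(72, list(
  q1_vr_experience = c(yes = 45, no = 27),
  q2_engaged = c(yes = 55, no = 17),
  q3_motion_sickness = c(yes = 4, no = 68),
  q4_best_performance_condition = c(both = 36, audio = 17, haptic = 10,
                                    none = 5, unsure = 4),
  q6_preferred_condition = c(both = 29, audio = 23, haptic = 13, none = 4,
                             unsure = 3),
  q8_interest = c(extremely = 42, fairly = 28, moderately = 2, slightly = 0,
                  not_at_all = 0)
))
sp <- summarize_questionnaire(published)
readr::write_csv(sp, "results/questionnaire_published_summary.csv")
message("published tallies: 29/72 preferring both -> ",
        sp$percentage[sp$item == "q6_preferred_condition" &
                        sp$category == "both"], "%")
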