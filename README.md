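# navkin

Movement-behavior analysis for within-subject VR navigation experiments with
multisensory (haptic x audio) obstacle feedback — and a seeded synthetic
cohort generator that makes the whole pipeline testable without access to
raw participant data.

## What it does

Wearable electronic travel aids signal nearby obstacles through vibration
(a belt) or sound (proximity beeps). The standard evaluation design is a 2x2
within-subject experiment: every participant walks an obstacle course under
all four feedback cells — none, haptic only, audio only, both — while the
system logs body position, head/trunk Euler angles, and collisions.
`navkin` implements the complete analysis of such experiments:

* **Telemetry IO** — canonical CSV schemas for trial logs, cohort manifests,
  metric tables, and questionnaires, with validating readers.
* **Preprocessing** — local quadratic (Savitzky-Golay) smoothing over a
  nominal 20-sample window, yaw unwrapping across the +/-180 degree seam,
  speed profiles, head-trunk yaw difference chi.
* **Per-trial metrics** — completion time; collision episodes (rising edges
  of the collision flag); trajectory length
  `L = sum_t ||p_{t+1} - p_t||` over the smoothed 2-D path; movement
  smoothness by spectral arc length (SPARC: negated arc length of the
  normalized speed spectrum up to an adaptive cutoff, threshold V = 0.05,
  f_max = 10 Hz); Shannon entropies H(theta_h) of head pitch and H(chi) of
  the head-trunk yaw difference over 1-degree bins, in bits.
* **Inference** — per-cell 1.5 IQR outlier screening (per-metric listwise
  removal); two-way repeated-measures ANOVA via the mixed model
  `metric ~ haptic * audio + (1 | participant)` with Satterthwaite
  denominator df for the continuous metrics (SPARC rank-transformed first);
  the Scheirer-Ray-Hare rank test (tie-corrected, chi-square reference) for
  collision counts; per-cell mean/SEM summaries and interaction-plot
  export.
* **Questionnaire descriptives** — counts, fractions, and integer
  percentages (half-up rounding) per closed item and category.
* **Synthetic cohorts** — a 2-D goal-directed walker with condition
  dependent detection geometry, avoidance steering, hesitation pauses, and
  head motion generates full telemetry for n participants x 4 cells at 72 Hz,
  with programmed effect directions (haptic: fewer collisions, lower
  head-pitch entropy, longer times and paths; audio: smoother trajectories;
  haptic x audio: attenuated path lengthening) plus a fast metrics-level
  generator for replicate simulation studies. Identical (config, seed) pairs
  regenerate byte-identical cohorts.

## Worked example

```r
library(navkin)

cfg     <- cohort_config(n_participants = 12, seed = 42)
cohort  <- generate_cohort(cfg)          # 48 telemetry trials + questionnaire
metrics <- compute_metrics_table(cohort) # 6 metrics per trial
analysis <- analyze_metrics(metrics)     # outlier screen + factorial tests

analysis$effects[analysis$effects$metric == "n_collisions", ]
#>         metric      effect statistic_kind statistic df1 df2   p_value
#> 1 n_collisions      haptic              H   36.5258   1  NA 1.507e-09
#> 2 n_collisions       audio              H    0.4484   1  NA 5.031e-01
#> 3 n_collisions interaction              H    0.4560   1  NA 4.995e-01

analysis$summaries[analysis$summaries$metric == "n_collisions", ]
#>         metric haptic audio mean   sem  n
#> 1 n_collisions  FALSE FALSE 5.25 0.411 12
#> 2 n_collisions  FALSE  TRUE 5.83 0.767 12
#> 3 n_collisions   TRUE FALSE 0.00 0.000  9
#> 4 n_collisions   TRUE  TRUE 0.50 0.151 12
```

The Scheirer-Ray-Hare table shows a strong haptic reduction in collisions
(H = 36.5 on 1 df, p ~ 2e-9): the cell means drop from ~5-6 collision
episodes per trial without the belt to ~0-0.5 with it, while audio feedback
leaves the counts essentially unchanged. The same `analysis`
object carries the mixed-ANOVA tables for completion time, trajectory
length, rank-SPARC, and both entropies, the outlier report per metric, and
per-cell summaries for interaction plots (`plot_interaction(analysis$summaries,
"SPARC")`).

The numbered scripts under `analysis/` run the same workflow at the full
study size (72 participants) and write every table under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R      # cohort + metrics.csv
Rscript analysis/02_movement_behavior.R    # cell summaries + figures
Rscript analysis/03_factorial_inference.R  # effect tables + outlier report
Rscript analysis/04_questionnaire.R        # questionnaire descriptives
Rscript analysis/05_simulation_studies.R   # calibration + power
```

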