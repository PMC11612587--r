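---
title: "Movement kinematics and factorial inference for multisensory VR navigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement kinematics and factorial inference for multisensory VR navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navkin)
```

## The problem this package addresses

Electronic travel aids for people with visual impairment convey obstacle
information through touch (e.g. a vibrotactile belt) or sound (proximity
beeps). A standard way to evaluate them is a within-subject experiment: each
participant walks an obstacle course under every cell of a 2x2 factor grid —
haptic feedback off/on crossed with audio feedback off/on — while the system
logs body position, head and trunk orientation, and collision events. The
analysis then asks how each modality, alone and combined, changes navigation
performance (completion time, collisions, trajectory length and smoothness)
and movement behavior (head-orientation variability).

`navkin` implements that full analysis as a reusable, tested pipeline:
telemetry IO, preprocessing, the six per-trial metrics, outlier screening,
the factorial tests, questionnaire descriptives, and — because raw
participant data of such studies is typically not deposited — a seeded
synthetic-cohort generator that reproduces the statistical structure the
analysis assumes, so every stage can be exercised and validated end to end.

## Per-trial metrics

Each trial log is a uniformly sampled time series (default 72 Hz) of body
position `(x, y, z)` in a room frame whose origin is the start position and
whose z axis is aligned with gravity, plus Euler angles for the head
(`psi_h`, `theta_h`, `phi_h`) and trunk (`psi_b`, `theta_b`, `phi_b`), and a
per-sample collision flag.

**Smoothing.** Position and angle series are smoothed by local quadratic
least squares (Savitzky-Golay) over a nominal 20-sample window before any
derivative is taken. A perfectly centered 20-point window does not exist, so
the window is realized as the nearest odd count — 21 points, 10 per side —
because only centered fits are unbiased at interior points. At the series
edges the window shrinks symmetrically; the first and last samples are
interpolated exactly (any quadratic through 3 points passes through them).
Yaw angles are unwrapped onto a continuous branch before smoothing and
re-wrapped to (-180, 180] afterwards: a regression across the +/-180 seam is
meaningless otherwise. The operator is linear and reproduces polynomials of
degree <= 2 exactly, which the tests verify.

**Trajectory length.** `L = sum_t ||p_{t+1} - p_t||` over the smoothed 2-D
body positions `p_t = (x_t, y_t)`; the vertical coordinate is retained in
logs but does not enter `L` or the speed profile.

**Smoothness (SPARC).** The speed profile `v_t = ||p_{t+1} - p_t|| / dt` is
Fourier-transformed (zero-padded by a factor 4, rounded up to a power of
two), the magnitude spectrum is normalized by its maximum, and the cutoff
`f_c` is the largest grid frequency below `f_max = 10` Hz whose normalized
magnitude exceeds `V = 0.05`. SPARC is the negated arc length of the
normalized spectrum up to `f_c`, with the frequency axis scaled by `1/f_c`.
Smoother movement concentrates the speed spectrum at low frequencies and
yields a less negative value. The implementation is validated against an
independently coded direct-DFT brute-force computation (agreement to ~1e-15)
and the index is invariant to amplitude scaling and time reversal.

One boundary case deserves a note: for a finite constant-speed segment the
padded spectrum is a Dirichlet kernel whose sidelobes exceed the 5%
threshold, so the converged value is about -2.46, not the -1 one might
expect from a pure-DC argument; the tests therefore pin the invariances and
the oracle agreement rather than a closed-form value. Relatedly, additive
band-limited noise lowers SPARC only once its spectral components rise above
the 5% threshold; in the monotonicity study the noise is sized accordingly
(per-sinusoid amplitudes 7.5-25% of the mean speed).

**Orientation entropy.** Head-pitch variability `H(theta_h)` and head-trunk
yaw-difference variability `H(chi)`, `chi_t = wrap(psi_{h,t} - psi_{b,t})`,
are Shannon entropies over 1-degree bins, in bits: `H = -sum p log2 p` with
`p` the relative frequency per occupied bin. Bins are anchored at integer
degrees (..., [-1,0), [0,1), ...) rather than at each trial's minimum, so
the discretization is identical across trials; the entropy is invariant to
full-turn shifts and bounded by log2 of the number of occupied bins.

**Counts and time.** Collision events are rising edges of the per-sample
flag — one count per continuous overlap episode — and completion time is the
log's time extent.

## Inference

Metrics are screened per metric and per condition cell with the boxplot
rule: an observation outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (type-7
quartiles) is excluded from that metric's model only (listwise per metric).
Screening within cells rather than pooled keeps a genuine condition effect
from being flagged as outlying; the pooled variant remains available.

Continuous metrics — completion time, `L`, rank-transformed SPARC (mid-ranks
for ties), and both entropies — are analyzed with a two-way
repeated-measures ANOVA realized as the linear mixed model
`metric ~ haptic * audio + (1 | participant)`, fitted by REML
(`lmerTest`), with Satterthwaite denominator degrees of freedom. The
Satterthwaite route is preferred because it remains valid under the mild
unbalance that outlier removal introduces; on balanced data with no
between-participant variance the F statistics coincide with the classical
two-way fixed-effects ANOVA (verified to 1e-6 in the tests).

Collision counts, the one discrete metric, get the Scheirer-Ray-Hare rank
test: all N observations are mid-ranked, factorial sums of squares are
computed on the ranks (type II, which equals the classical decomposition on
balanced data), and each effect's statistic `H = SS_effect / MS_total` is
referred to chi-square with 1 df, after the tie correction
`D = 1 - sum(t^3 - t)/(N^3 - N)`. Complete ties return `H = 0`, `p = 1`
without dividing by a vanishing `D`. The chi-square reference is asymptotic;
with N = 288 observations it is well inside its comfort zone, and the
calibration study below confirms it empirically. Alpha is 0.05 throughout
with no multiple-testing correction, matching per-metric reporting practice.

Questionnaire items are purely descriptive: per closed item and category,
count, denominator, exact fraction, and the integer percentage with half-up
rounding (`floor(x + 0.5)`) — the survey-reporting convention under which
45/72 = 62.5% reports as 63% (R's own `round` would give 62).

## The synthetic cohort generator

The generator is an explicit stand-in for human participants, not a claim
about human motor control. A 2-D goal-directed walker steps at the telemetry
rate along a 40 m out-and-back corridor (20 m per leg, turn at the far end)
past 8 staggered obstacles (radius 0.35 m, offset +/-0.35 m from the
midline). Its heading relaxes toward the active waypoint at 2.5 /s, is
repelled from detected obstacles, and carries Gaussian noise; speed is the
preferred 1.0 m/s modulated by AR(1) noise (time constant 0.4 s). Avoidance
steering persists for ~0.7 s after an obstacle leaves the detection
geometry, standing in for short-term spatial memory; without it a walker
stops evading the moment an obstacle passes out of the sensor's angular
coverage while still inside clearance.

Condition effects are mechanistic, so all six metrics emerge from one
mechanism:

* **haptic on** — belt-style detection over the full 89-degree horizontal
  field of view at 2.5 m, a higher avoidance gain (wider detours, longer
  `L`), hesitation pauses (hazard 0.35 /s while detecting, ~0.5 s at 15%
  speed; longer completion times), and a smaller head-pitch oscillation
  (8 -> 5.5 degrees; lower `H(theta_h)`);
* **audio on** — a single head-direction detection ray (+/-15 degrees,
  2.5 m) and lower heading/speed noise (speed noise 0.16 -> 0.085), giving
  smoother speed profiles and higher SPARC;
* **both** — haptic detection geometry with an attenuated avoidance gain
  (95 vs 140 deg/s), shrinking the haptic path-lengthening increment (the
  programmed interaction);
* **neither** — only the short "residual vision" detector (1.1 m, frontal
  coverage) remains. Residual vision stays active under every condition —
  feedback augments rather than replaces it, which keeps the audio cells'
  collision counts near the no-feedback baseline (the head ray alone would
  otherwise be a downgrade) — so collisions concentrate in the cells without
  haptic feedback (~5-6 per trial versus ~0.5 with the belt).

Head yaw adds a +/-30 degree scanning oscillation to trunk yaw; head pitch
oscillates at 0.35 Hz. Collisions are flagged per sample while the walker
disc (0.25 m) overlaps an obstacle disc — the walker passes through, as in
VR — and counted once per overlap episode. A trial that misses the 120 s cap
is flagged incomplete and excluded from metrics with a warning.
Between-participant heterogeneity enters as lognormal multipliers on
preferred speed (CV 0.08), pitch amplitude (CV 0.15), hesitation propensity
(CV 0.30), and noise scales (CV 0.15) — the random-intercept structure the
mixed model assumes. Each participant's condition order is drawn uniformly
from the 24 orderings. Everything is driven by one seed; identical (config,
seed) pairs regenerate byte-identical cohorts.

The sampling rate (72 Hz, headset-typical) and all mechanism constants are
configuration, not hard-coded. No published effect sizes exist for these
metrics on raw data, so the defaults were chosen once for detectability at
the study's size and then frozen: +/-0.5-0.6 within-subject SDs for the main
effects, with the trajectory-length pair (haptic +0.8, interaction -0.7) set
so that both the type-III marginal haptic effect and the interaction retain
at least ~90% power at 72 participants. The collision log-rate shift is
-0.5 around a baseline Poisson rate of 3.

A second, metrics-level generator draws per-trial metric values directly
from the assumed stochastic model (baseline + within-SD-scaled participant
intercept, programmed shifts, Gaussian noise; Poisson counts on a log-rate).
Replicate simulation studies use it because it isolates exactly what those
studies measure — the operating characteristics of the inferential layer —
at a small fraction of the cost of full telemetry; the telemetry walker
remains the end-to-end route and is checked for the same effect directions.

**What passing tests do and do not show.** The generator reproduces the
design (2x2 within-subject, randomized order), the effect directions, the
repeated-measures dependence structure, and plausible magnitudes. It does
not reproduce human gait spectra, fatigue or learning across the four
trials, veering behavior of people with visual impairment, or realistic
collision-count distributions in feedback-free navigation. Green tests
therefore validate the pipeline's correctness and calibration, not any
empirical claim about navigation with assistive devices.

## Numerical choices and degenerate inputs

* Angles are stored in degrees and wrapped to (-180, 180]; the wrap maps
  -180 to +180.
* Entropy bins anchored at integer degrees (not at each trial's minimum):
  reproducible across trials, at the cost of a bin-phase sensitivity shared
  by any fixed-grid histogram. A series sitting exactly on a bin boundary is
  assigned by `floor`.
* SPARC zero-padding factor 4 (next power of two). An all-zero speed
  profile or a spectrum never exceeding the threshold raises an error rather
  than returning a value.
* The SRH tie correction divides by `D`; the all-tied case short-circuits to
  `H = 0` before any division.
* Mixed fits ignore the singular-boundary warning (a zero variance estimate
  is a legitimate estimate); a fit that errors out is reported as a failure
  naming the metric, with no silent fallback.
* Outlier fences collapse to the value itself when IQR = 0, so constant
  cells flag nothing.

## Study sizes in the tests and the acceptance script

Type-I calibration uses 500 replicate null cohorts for the mixed ANOVA and
2000 for SRH (rejection-rate standard errors ~0.010 and ~0.005 at the
nominal 0.05); power and direction recovery use 100 replicate metric-level
cohorts; the telemetry direction study uses 60 full cohorts in the
acceptance script and a single 16-participant cohort plus 30 metric-level
replicates in the routine test suite. These sizes were chosen so each
check's Monte-Carlo error is small against its acceptance band.

## Known limitations

* The walker is 2-D and disc-shaped; no gait cycle, so SPARC differences are
  driven by programmed noise scales rather than biomechanics.
* The Satterthwaite/mixed-model route assumes Gaussian residuals for the
  continuous metrics; the pipeline rank-transforms SPARC (whose raw residuals
  are typically non-normal) but applies no runtime normality gate — which
  test each metric receives is fixed configuration.
* SRH treats the 288 observations as exchangeable under the null; with
  participant intercepts present it is conservative rather than anticonservative
  (its null calibration study uses i.i.d. counts accordingly).
* Questionnaire free-text items are stored verbatim and never analyzed.
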