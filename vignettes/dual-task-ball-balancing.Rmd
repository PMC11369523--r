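---
title: "Dual-task ball balancing: models, features and analyses"
author: "dtball maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-task ball balancing: models, features and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtball)
```

# The assessment

In the dual-task ball-balancing assessment a seated participant holds a
tablet parallel to the ground and tilts it to keep a virtual ball inside
an inner target circle. The ball is never perturbed unless the tablet
moves. Each participant completes one 20 s trial with the balancing task
alone (single task, ST) and one 45 s trial while concurrently repeating
heard digit sequences in reverse (dual task, DT). Performance is read
out entirely from the tablet's inertial measurement unit (IMU): the
triaxial accelerometer and gyroscope determine the tablet's tilt, the
tilt drives a Newtonian model of the ball, and both the ball trajectory
and the raw inertial signals are summarized into features. The
scientific quantity of interest is the *dual-task cost* — the
percentage performance change from ST to DT,
$\mathrm{DTC} = -100\,(\mathrm{DT}-\mathrm{ST})/\mathrm{ST}$ — read as a
marker of how much spare cognitive capacity the motor task leaves.

`dtball` implements the full analysis chain — session I/O, signal
conditioning, the ball model, feature extraction, cohort statistics and
cross-validated classification — together with a closed-loop simulator
that generates complete synthetic cohorts, so that every stage is
testable without clinical data.

# Signal conditioning

Trials pass through a fixed chain with these defaults, each exposed as a
parameter:

* **Trim** (`trim_s = 1` s): one second is dropped from each end of a
  recording to remove tablet-positioning artifacts.
* **Duration gate** (`min_duration_s = 10` s): trials shorter than 10 s
  after trimming are discarded (strictly-below rule; exactly 10 s is
  kept). Rejections are logged in the run manifest.
* **Uniform resampling** (`fs = 100` Hz): tablet IMU streams can be
  unevenly sampled, which distorts frequency-domain features; channels
  are interpolated onto a uniform grid with a shape-preserving piecewise
  cubic (Fritsch–Carlson), falling back to linear interpolation below 4
  samples. No extrapolation is performed; output length is
  $\lfloor T f_s \rfloor + 1$.
* **Band-pass filtering** (0.1–40 Hz, order-4 Butterworth IIR): applied
  forward–backward (zero phase) so temporal features are not phase
  shifted; the effective attenuation order doubles. The same band is
  applied to accelerometer and gyroscope channels, since both are
  spectrally featurized.
* **Calibration**: an affine per-axis correction
  $\mathrm{gain}\times(\mathrm{channel}-\mathrm{offset})$. The default
  estimator uses a static epoch: gyroscope offsets are static means and
  a shared accelerometer gain references the gravity magnitude to
  $g$. Explicit parameters may be supplied instead.

The gate is applied after trimming, so it protects the downstream
windowed feature computations from short usable spans.

# Tilt and the virtual ball

**Tilt estimation** treats the IMU data as rigid-plane rotation (roll
about the screen x axis, pitch about y). The accelerometer gives
gravity-referenced angles, $\mathrm{roll} = \operatorname{atan2}(a_y,
a_z)$ and $\mathrm{pitch} = \operatorname{atan2}(-a_x,
\sqrt{a_y^2+a_z^2})$; the gyroscope gives angular rates. A complementary
filter fuses them with accelerometer weight 0.02 per step at 100 Hz —
gyro integration carries the short-term dynamics while the accelerometer
pins the low-frequency reference. Because band-passing removes the DC
gravity component, tilt is always estimated from the pre-filter stream.
Near free fall ($|a| < 0.1g$ for more than 0.5 s) the accelerometer term
is down-weighted tenfold and a warning raised.

**Ball dynamics.** The ball obeys
$\ddot{x} = \kappa\, g \sin(\mathrm{pitch}) - c\,\dot{x}$ (y analogous
with roll), with rolling factor $\kappa = 1$ (point mass; $5/7$ would
model a rolling solid sphere), light viscous damping $c = 0.05\,
\mathrm{s^{-1}}$, and the sign convention that tilting toward $+x$ rolls
the ball toward $+x$. Physical displacement maps to screen units through
`screenScale` (default 0.585 normalized units per metre, chosen so a
sustained 5° tilt carries the ball from center to the outer edge in
about 2 s). The outer circle has normalized radius 1; by default the
inner circle is half the outer and the ball radius 0.05 (the app's true
ratios are not published; both are configurable). At the boundary the
ball is clamped to the rim with the outward velocity component zeroed,
which keeps the normalized resultant displacement within $[0, 1]$.

Integration is exact per step for tilt held constant across the step
(the per-axis dynamics are a linear ODE, solved with an exponential
integrator) with the drive acceleration trapezoid-averaged over each
step, giving second-order convergence on smooth tilt. With constant tilt
and zero damping the trajectory reproduces
$\tfrac12 g \sin\theta\, t^2$ to machine precision.

**Whole-test trajectory.** The ball trajectory is derived from the
*untrimmed* stream: the ball's initial state at the start of the trial
is known exactly (center, at rest), whereas after trimming the app-side
ball state at the trim boundary would be unknown — and with nearly
undamped dynamics an initial-state error never decays. Trimming remains
in force for the inertial-sensor features, where it matters for
artifact removal and where no state is being integrated.

# Features

**Ball-position features** are computed on the normalized trajectory:

* *Percentage of time in circle* — the fraction of samples whose
  resultant displacement is strictly below
  $\mathrm{innerRatio}\times\mathrm{outer} - \mathrm{ballRadius}$,
  times 100. A *perfect score* is 100%; because a tablet left flat on a
  table scores perfectly, `excludePerfectScores()` supports the
  sensitivity re-run that drops flagged participants while leaving the
  main table untouched.
* *Radial symmetry* — the sum of first differences of the resultant
  displacement. Read literally this telescopes to
  $r_\mathrm{end}-r_\mathrm{start}$, which discards everything between
  the endpoints; the default therefore sums absolute first differences
  (total radial movement), with the literal mode available and the mode
  recorded alongside the value.
* *Epoch statistics* — time-in-circle per non-overlapping 5 s epoch,
  summarized as mean, sample SD and mean first difference (intratest
  change). A trailing partial epoch at least half an epoch long is
  kept; shorter remnants are dropped. With a single epoch the spread
  statistics are undefined and reported missing.
* *Spectral summaries* — Welch PSD (Hann window, segment length
  $\min(n, 1024)$, 50% overlap, per-segment mean removal; parameters
  fixed for reproducibility), from which come the median frequency
  (50% of in-band power), the 95% spectral edge frequency, and — for
  the IMU features — the spectral entropy (Shannon entropy of the
  normalized PSD over $\log$ bin count, in $[0,1]$). By construction
  SEF95 never falls below the median frequency.
* *Stabilogram measures*, the standard center-of-pressure summary set
  applied to the demeaned ball displacement, each in resultant
  (`mean`), `x` and `y` variants: mean sway distance (mean absolute
  deviation), resultant sway distance (RMS), sway length (path length;
  per axis, summed absolute increments), sway velocity (length over
  duration), mean sway frequency (velocity over $2\pi\times$ mean
  distance — the rotational convention), and the sway area (area swept
  per unit time by the centroid vector, triangle-sum estimate).
  `radial_frequency`, which appears in some analyses of this task, is
  an alias for the resultant mean sway frequency.

**Inertial-sensor features** come from the band-passed channels: RMS
acceleration (vector magnitude and per axis), RMS angular velocity
(magnitude, x, y), the spectral trio for the acceleration and
angular-velocity magnitude signals, sway path lengths of the x and z
acceleration axes, the triangle-sum sway area on the (x, z)
acceleration plane, a normalized sway jerk, and the 95% confidence
ellipse area $\pi \cdot 5.991 \cdot \sqrt{\det \Sigma}$ of (x, z)
acceleration. The sway jerk uses a dimensionless normalization,
$\sqrt{\tfrac12 T \int (j_x^2 + j_z^2)\,dt}\,/\,L$ with $j$ the
time-derivative of the acceleration trace and $L$ its path length; the
exact construction of this measure is not standardized, so the
convention is documented here and pinned by tests.

Per participant, every feature is computed under ST and DT and combined
into the dual-task cost. A zero ST value yields a missing cost rather
than $\pm\infty$; rows with missing costs are dropped pairwise per
analysis, not listwise. The assembled table is a
`SummarizedExperiment` subclass (assays `st`, `dt`, `dtc`; participants
as columns; metadata as `colData`), flattened to CSV with `_st`, `_dt`,
`_dtc` suffixes.

# Statistics

Cognitive outcome measures are dichotomized as: consensus cohort status
(healthy vs MCI ∪ ADRD; the three-level labels are also available);
MMSE total strictly below 28 = impaired; RAVLT long-delay score below
an age-bucket cut; FAQ total ≥ 6 = functionally impaired. The RAVLT
age-bucket cuts shipped with the package are clearly-marked 5-year
placeholder values standing in for published norms tables and should be
replaced with the user's normative source via `defaultThresholds()`.

The test battery mirrors the assessment's analysis plan: Wilcoxon
signed rank across task conditions; Wilcoxon rank sum between impaired
and intact groups; Spearman association of features with MMSE and
RAVLT; ANCOVA (`feature ~ group + age`) for group effects controlling
for age, applied across all label schemes; and the FAQ independence
analysis (`feature ~ faq + {MMSE | RAVLT} + age`), asking whether a
feature carries functional-impairment information beyond cognition and
age. A within-subjects mixed-effects reading of the age adjustment is
not meaningful for a cross-sectional design, so the fixed-effect ANCOVA
is used throughout. Rank tests use the exact distribution at small n
without ties and the tie-corrected normal approximation otherwise (the
`stats` defaults). `statsReport()` returns one tidy row per (feature,
condition, scheme, test) with raw p-values and a Benjamini–Hochberg
adjusted column per test family; findings in this literature are
typically reported unadjusted, so both are shown.

# Classification

Binary cognitive status is classified with L2-free logistic regression
and wrapper-based sequential forward selection (SFS), validated with
stratified 10-fold cross-validation. Selection is *nested*: inside each
outer training fold, candidates are standardized with training-fold
statistics and greedily added by inner 5-fold CV accuracy, stopping
when no candidate improves accuracy by more than 0.001 or when 10
features have been selected. Held-out predictions are pooled into a
single confusion matrix; accuracy, sensitivity, specificity, PPV and
NPV are reported (degenerate cells as 0.00 with a flag). Candidate sets
per scope (`st`, `dt`, `dtc`, `all`, `age_only`) contain the scoped
base features, all pairwise interactions among them, and age and sex
(except `age_only`).

With ~45 base features the interaction-complete candidate pool runs to
about a thousand columns, which makes exhaustive wrapper selection
impractical; each training fold therefore prescreens candidates to the
`max_candidates = 40` with the largest standardized class separation
before SFS begins. The screen uses training rows only, so the held-out
fold never influences selection — the leakage canary tests verify this
(a feature equal to the held-out fold index classifies at chance).
Sex-stratified models (male-only, female-only) are fitted alongside the
all-data model, and the `mean` stratum is the unweighted mean of the
male and female metrics.

# The synthetic cohort

The generator's participant is a delayed proportional–derivative
controller closing the loop around the *displayed* ball: the app
derives the on-screen ball from its own noisy sensor stream in real
time, so the simulator synthesizes accelerometer and gyroscope signals
(gravity projection plus white sensor noise; interval-averaged tilt
rate plus noise), runs the same complementary tilt fusion in-loop, and
drives the ball with that estimate. This is a modeling choice, not a
claim about human physiology — it is the simplest mechanism that
produces the assessment's key statistical structure:

* motor noise, modeled as slow postural drift (white noise through two
  first-order poles, correlation ≈ 0.7 s) because the ball's inertia
  low-passes fast tremor;
* a sensorimotor reaction delay and a first-order motor lag (0.15 s);
* under dual task, Poisson control interruptions (frozen tilt command,
  default 0.8 s long) standing in for attention captured by the
  concurrent cognitive task.

Cohorts (132 healthy / 116 MCI / 126 ADRD, plus one participant with a
missing cohort label; 56% female; ages 60–85 with cohort-graded means
near an overall mean of 73) share a latent impairment factor $z$ that
scales the controller's noise, delay and interruption rate and
generates MMSE, RAVLT and FAQ scores from cohort-conditional truncated
discretized normals. The score noise terms are set so the mixture-level
MMSE / RAVLT-long-delay correlation is modest (≈ 0.6), matching what
these instruments show in older adults. Sensor noise defaults (accel
0.02 m/s², gyro 0.1 °/s) are typical consumer-tablet MEMS figures.
Timestamps carry a small jitter (SD 0.1 ms) to emulate uneven tablet
sampling and exercise the resampler; the jitter is kept small because
re-deriving a marginally stable double integrator from unevenly sampled
data is exquisitely sensitive — with noiseless sensors and uniform
sampling the offline reconstruction reproduces the recorded ball to
machine precision, and this is pinned by a test.

`calibrateCohort()` tunes, per cohort, the motor-noise SD against a
single-task target and then the interruption rate against a dual-task
target (grid search with midpoint refinement, measured through the
package's own derived-trajectory path). The default targets are the
group means reported for the clinical validation cohort the simulator
emulates (ST 92.6 / 87.5 / 77.5%; DT 70.2 / 63.7 / 63.9%). What the
simulator does *not* model: physiological tremor spectra, touchscreen
contact dynamics, 3-D translation of the tablet, learning effects
within a trial, and the true inter-feature covariance of clinical data.
Passing tests on this cohort therefore demonstrate the pipeline's
correctness and the qualitative reproducibility of the group-level
findings, not numerical equality with any clinical sample.

# Numerical choices and limitations

* Welch segment length, window and overlap are fixed; changing them
  changes spectral features and should be done consistently.
* The in-circle threshold uses a strict inequality; trajectories
  resting exactly on the threshold count as outside.
* Ties in rank tests are mid-ranked; constant inputs yield missing
  correlations rather than errors.
* The per-trial problem sizes used in the shipped tests and in
  `scripts/acceptance.R` (a 375-participant cohort, 16 calibration
  trials per grid cell, 1000-replicate null calibrations, 20
  permutation replicates) were chosen as the smallest sizes at which
  the group-level structure is stable.
* Classification metrics depend on the fold seed through the usual CV
  variance; reports record seed, folds and the per-fold selected
  features.

```{r example, eval = FALSE}
# A small end-to-end run
cfg <- defaultConfig()
cfg$simulate$n_per_cohort <- c(healthy = 20, MCI = 20, ADRD = 20)
cfg$out <- tempfile("dtball-run")
man <- runPipeline(cfg)
```
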