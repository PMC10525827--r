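---
title: "Quantifying stimulus-evoked movement in chicken embryos from pose tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stimulus-evoked movement in chicken embryos from pose tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

A chicken embryo filmed in ovo cannot report anything; whether it responds
to a noxious mechanical stimulus has to be read off its movements. The
experimental design this package supports films the embryo at 50 frames
per second through a window in the shell, records a baseline period (two
minutes for embryonic days (ED) 15–18, three minutes for ED9–14), then
applies two stimuli at the beak base in randomized order — a noxious
pinch and a light touch as negative control — each followed by an
observation period of which the first 120 s are analyzed. Markerless pose
estimation turns each video into a *pose track*: for every labelled body
part and frame, an x coordinate, a y coordinate (pixels, y down) and a
tracking likelihood in [0, 1].

`embryokin` owns everything downstream of the tracking network: quality
control, per-frame kinematic parameters, windowed interval statistics,
baseline-versus-post contrasts, and ethogram responder tables. It also
ships a synthetic cohort generator so that every stage can be tested
against known ground truth, since raw experimental videos of this kind
are rarely deposited.

## Quality control

Two mechanisms precede all kinematics:

* **Likelihood cutoff** (`apply_likelihood_cutoff`, default 0.75): a
  tracked point with likelihood below the cutoff becomes missing. The
  boundary is retained — masking applies to `likelihood < cutoff`. The
  convention matters for reproducibility and is pinned by a unit test;
  either boundary reading is defensible, and `<` makes a cutoff of 0 a
  guaranteed no-op.
* **Outlier screening** (`flag_outliers`): mislabelled frames show up as
  points far outside the body part's data cluster in x–y space. The
  automated screen flags frames whose distance from the label's spatial
  median exceeds the median distance plus `k` robust standard deviations
  (MAD, default `k = 6`). When the MAD is zero — a perfectly stationary
  reference point — no flags are raised, avoiding division-by-zero false
  positives. A verbatim manual exclusion list is supported as the second
  rule.

Flags are *advisory*: they become missing values only through
`apply_exclusions`. `run_pipeline` deliberately does **not** apply the
automatic screen by default (`outlier_k = NA`). A landmark that genuinely
moves — an opening beak, a motile head — sits many robust SDs from its
spatial median exactly when the behavior of interest happens, so blind
application of a position screen deletes the response being measured (on
simulated cohorts it reliably excluded the first post-pinch interval).
Position-based screening is a review aid, mirroring visual cluster
inspection; apply it per label after looking.

Missing cells are represented as coordinates `NA` with likelihood 0, and
downstream exclusion logic owns what to do about them.

## Kinematic parameters

Three per-frame parameters, computed on role-resolved landmarks
(`bind_scheme` maps raw label names onto roles; on ED9 the tarsus must
stand in for the translucent metatarsus as the leg landmark):

* **Beak distance** (px): Euclidean gap between the upper and lower beak
  landmarks, \(d = \sqrt{(x_u-x_l)^2 + (y_u-y_l)^2}\).
* **Beak angle** (deg): unsigned angle at the beak fulcrum \(P_0\)
  between the rays to the upper (\(P_1\)) and lower (\(P_2\)) beak
  points, \(\alpha = \operatorname{atan2}(|\det(n_2; n_1)|,\,
  n_2 \cdot n_1)\) with \(n_1, n_2\) the unit vectors along the rays.
  This equals the clamped arccos of the dot product and lies in
  [0, 180]; the atan2 form is numerically stable near 0 and 180. If
  \(P_1\) or \(P_2\) coincides with \(P_0\) the angle is undefined and
  emitted as missing rather than 0 — a silent 0 would bias interval sums
  downward.
* **Movement** (px): displacement of one landmark between strictly
  consecutive frames. If either endpoint frame is missing the step is
  missing; displacement is never computed across a masked gap, because a
  two-frame jump is not the same quantity as two one-frame steps.
  Stationary reference points on the egg or holder give a negative
  control series that is identically zero on noise-free data.

All three parameters propagate missingness from their input landmarks,
are invariant under global translation, and behave as expected under
global scaling (distances scale, the angle does not).

## Windowed interval statistics

Analysis proceeds on 30-s intervals: `round(30 × frame_rate)` frames per
interval — 1500 at 50 fps; the formula, not the constant, is the rule, so
a 25 fps recording gives 750-frame intervals. For each stimulus, four
post-stimulus intervals (0–30 … 90–120 s) start at the *release* frame,
the moment the clamp leaves the beak; pre-stimulus intervals are tiled
backward from the onset frame across the baseline period.

Per interval and parameter:

1. **Exclusion rule** (pre-imputation): if more than 5% of the values
   are missing the interval is excluded. "More than" is strict — 75 of
   1500 missing is retained, 76 is excluded.
2. **Imputation**: each contiguous missing run of length \(g\) is filled
   with one constant, the median of the \(k = \max(1, \lceil g/2 \rceil)\)
   nearest observed values on each side, pooled (one-sided at interval
   edges). "Half of the adjacent data" admits several readings; this one
   is symmetric, local, uses only observed values (fills never feed later
   fills), and reduces to the nearest-neighbour median for single-frame
   dropouts. Observed values are never altered.
3. **Interval sum**: the arithmetic sum of the (imputed) values — total
   pixels travelled for movement parameters, summed gap or angle for the
   beak parameters.

The **baseline** of each stimulus is the median of the sums of the four
intervals immediately preceding its onset; excluded intervals are dropped
from the median (imputing a whole interval from its neighbours would
manufacture data), and if all four are excluded the baseline is missing.
With a 3-min baseline more than four tiles exist, but the statistic still
uses the four closest to the stimulus. The baseline travels as a single
"BL" cell alongside the four post intervals — the five analysis cells per
stimulus.

For movement ("step") series, the step between frames \(t\) and
\(t{+}1\) is attributed to the interval containing \(t\); an interval
therefore aggregates the movement initiated within it.

## Contrasts

Interval sums are repeated measures: every embryo contributes all cells.
`fit_interval_model` fits a linear mixed model with one fixed cell mean
per stimulus × interval combination and a random intercept per embryo
(REML, `lme4`); at least two embryos are required, otherwise the design
cannot separate the embryo effect from the residual and an explicit error
is raised. `marginal_contrasts` forms pairwise differences of the
estimated marginal means (`emmeans`, Satterthwaite df) with
multivariate-t adjustment over the declared family — the exact
Tukey-style family-wise correction for an arbitrary contrast set; a
single-comparison family keeps its unadjusted p. The default family
mirrors the comparisons one would report: each post interval against its
stimulus's baseline, and pinch against touch at each post interval.
Significance is called at α = 0.05 (configurable).

Real interval sums violate normal-theory assumptions (skewed residuals,
heteroscedasticity, outliers); analyses of this design have used robust
(Huberized) mixed models for that reason. Rather than replicate specific
robustness weights, the package pairs the standard REML fit with a
**paired sign-flip permutation contrast** (`permutation_contrast`): the
within-embryo difference of two cells is the unit, the paired
t statistic is the test statistic, and its null distribution comes from
random sign flips, \(p = (1 + \#\{|T_{perm}| \ge |T_{obs}|\}) / (1 +
n_{perm})\). Max-T over a family with shared flips gives family-wise
adjusted p values. The permutation p is exact under exchangeability
regardless of the error distribution, and both routes are reported when
`stats_method = "both"`. The tie comparison uses a relative tolerance of
1e-8 so that affine rescaling of the response cannot flip an
exact-equality permutation; p values are thereby invariant under
\(y \mapsto ay + b\), \(a > 0\).

## Ethogram

Manual observation distinguishes four beak behaviors that pose tracking
alone cannot separate: *Beak Shift*, *Mandibulation*, *Beak Opening* and
*Wide Beak Opening*. Annotations (trial, behavior, frame stamp) are
validated against this closed set. `tally_behaviors` assigns each event
to a window — for manual scoring the baseline is the single 30-s interval
before onset, the post window the four 30-s intervals from release — and
reports, per group × stimulus × window × interval × behavior, the event
count, the responder count (embryos with ≥ 1 event) and the responder
percentage. Percentages are rounded half-away-from-zero to one decimal:
13/16 → 81.3, 3/16 → 18.8, 1/16 → 6.3; banker's rounding would print
81.2 and disagree with how such tables are conventionally reported.

`detect_candidate_openings` proposes annotation candidates from upward
threshold crossings of the beak-distance series, debounced by a minimum
separation (default 25 frames = 0.5 s). Candidates are strictly advisory
and never enter the tally: the ethogram is observer-defined.

## The synthetic cohort generator

`simulate_cohort` generates pose-track cohorts with the statistical
structure the analysis assumes, plus ground truth for every stage. The
defaults are the study conditions: 16 embryos, 50 fps, ED-dependent
baseline duration, two stimuli in randomized order, 3-min observation
windows of which 120 s are analyzed.

* **Skeleton and noise**: each landmark rests at a fixed skeleton
  position with isotropic Gaussian jitter (SD 0.5 px — sub-pixel, the
  precision a well-trained tracking network achieves on a static scene).
* **Evoked response**: the pinch adds beak-opening events — trapezoidal
  pulses in the beak gap (5-frame rise, 30-frame plateau, amplitude
  8 px), the simplest waveform with controllable total open time for
  "swift" openings. The event rate starts at 8 events/30 s and halves
  each interval, reproducing a response concentrated in the first 30 s
  that decays over the 120-s window. Touch adds none by default, making
  pinch-versus-touch the designed discovery.
* **Embryo structure**: each embryo's resting gap is offset by
  N(0, 1 px), the random-intercept structure the mixed model recovers.
* **Spontaneous motility**: eye corner, elbow and leg make smooth
  out-and-back excursions (2 bouts/min, 3 px amplitude, 0.5–2 s),
  emulating stimulus-independent motility so that movement parameters
  are not trivially zero off-stimulus.
* **Tracking imperfections**: isolated likelihood dropouts (1% of
  frames), dropout bursts (0.5/min, mean length 10 frames), and rare
  gross outlier frames (rate 5e-4, 300 px displacement at high
  likelihood).

Ground truth records every injected event, dropout and outlier frame,
and the noise-free beak-gap interval sums; on noise-free, dropout-free
parameterizations the pipeline reproduces those sums exactly, and a
pulse of amplitude \(A\), rise \(r\) and plateau \(h\) contributes
exactly \(A(h + r)\) px·frames.

What the generator does **not** emulate: correlated tracking error
(network failures cluster on occlusions, not at random), perspective and
lens distortion, drift of the "stationary" reference points, embryo
growth across EDs, any coupling between beak, head and limb movement,
and observer disagreement in the ethogram. Passing tests therefore show
that the *pipeline arithmetic and inference machinery* behave as
specified under realistic noise, dropout and effect structure — not that
the biological conclusions of any particular experiment are correct.

## Numerical and design choices

* Frames are 0-based everywhere (files, designs, flags), matching the
  pose CSV dialect; R vector index `i` is frame `i − 1`.
* Pose CSVs are written with 17 significant digits, which round-trips
  IEEE doubles exactly; the simulator rounds coordinates to 1e-6 px so
  files are byte-stable across runs at a fixed seed.
* Masked cells are written as empty coordinate fields with likelihood 0,
  so read ∘ write is the identity on valid tracks.
* Degenerate inputs error loudly rather than guess: post windows past
  the end of the recording, an all-missing interval, a one-embryo
  design, unknown behavior names, cutoffs outside [0, 1].
* Every randomized quantity flows from one seed: a cohort draws
  per-embryo sub-seeds from the master seed, and `run_pipeline` rolls
  everything into its manifest so a run is reproducible byte-for-byte.

## Problem sizes in the test suite

The suite validates parameter recovery on 200 simulated 16-embryo
cohorts at the default effect size (pulse amplitude 16× the frame-noise
SD, decaying event rate) and calibrates the permutation test's type-I
error on 1000 null replicates of 16 paired interval sums with 999 flips
each — sizes chosen to give stable rates while keeping a full test run
in the minutes range. Unit tests use toy cohorts of 1–8 embryos and, for
end-to-end determinism, 4-embryo runs with a 120-s observation window.

## Limitations

* The robust-distance outlier screen is a stand-in for visual cluster
  review; its `k` is not derived from data and it cannot distinguish a
  mislabelled frame from a genuine large excursion. It is therefore not
  auto-applied.
* The mixed model is a standard REML fit, not the Huberized robust
  variant; with heavy-tailed residuals the permutation route is the one
  to trust.
* The imputation reading ("half of the adjacent data") is one of several
  defensible operationalizations; alternatives (per-value windows,
  interpolation) would differ on long gaps, which the >5% exclusion rule
  keeps rare.
* Ethogram tallies are only as good as the annotations; the candidate
  detector finds threshold crossings of one series and will miss
  behaviors defined by shape (tongue movement) rather than gap size.
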