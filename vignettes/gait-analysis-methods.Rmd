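---
title: "Methods: 3D gait and allodynia quantification for the SNL rat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D gait and allodynia quantification for the SNL rat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratgait3d)
```

## The measurement problem

Unilateral L5 spinal nerve ligation (SNL) produces mechanical allodynia
without gross motor deficit, so the locomotor phenotype lives in subtle
kinematics: vertical instability of the operated hind-limb joints, a
lengthened ipsilateral step, prolonged double support, and broken
left–right swing symmetry. `ratgait3d` computes these from 3D marker
trajectories recorded during treadmill walking at 12 m/min (20 cm/s), with
ten skin markers (iliac, hip, knee, ankle, 5th metatarsophalangeal joint ×
both hind-limbs). The package consumes *reconstructed* coordinates; camera
calibration and triangulation are out of scope.

Conventions, fixed throughout: x = direction of progression, z = vertical,
belt surface z = 0; units cm and s; stance = [touchdown, lift-off), swing =
[lift-off, next touchdown) — half-open, so each instant belongs to exactly
one phase.

## Gait model and metrics

**Events and windowing.** Touchdowns/lift-offs are either entered manually
(the reference method for this assay; manual tables always override
detection) or detected from toe height: lift-off at an upward crossing of
`z_thr` (default 0.15 cm) with positive vertical velocity, touchdown at a
downward crossing with non-positive velocity. A hysteresis band (0.05 cm)
and a minimum phase duration (0.05 s) debounce noise-induced phases; the
toe track is smoothed with a 5-frame moving average first, and event times
are refined by linear interpolation of the crossing so they are not
quantized to the frame grid. Recording both event kinds at the *same*
threshold keeps the stance-boundary bias symmetric (about 2 ms per event at
the default toe trajectory shape) rather than inflating stance at one end.
Analysis uses the first 10 complete left cycles ("10 steps" is read as 10
strides per limb, configurable); the right-limb window is the same time
span. Ten strides at 0.64 s cycles is a 6.4 s window.

**Belt frame.** On a treadmill the animal is stationary on average, so
distances are measured in the belt frame, `x_belt = x + v_belt · t`, where
treadmill walking looks like overground walking. Stride length is the mean
belt-frame distance between consecutive same-limb contacts (identically
`v_belt · T` for a stationary-on-average walker); step length is the
distance to the immediately preceding contralateral contact. The contact
position is sampled 0.02 s after touchdown (inside stance, clear of the
landing transient). The published "heel" lengths are computed from the toe
(mtp5) marker: the marker set contains no heel marker, so the toe is the
contact proxy — a deliberate, documented substitution, not a guess at the
original instrumentation.

**Fluctuation.** The top-minus-bottom height of a joint marker is computed
per cycle (`max z − min z` within [touchdown, next touchdown)) and averaged
over the window. A whole-trial range would conflate slow postural drift
with within-stride fluctuation; the per-cycle reading matches "fluctuation
during walking" and the trial-scope alternative remains available
(`fluctuation_scope = "trial"`).

**Both-foot contact.** The cumulative length of the intersection of the
two stance-interval unions, clipped to the window. The published
magnitudes (1.0–2.0 s) exceed a single 0.64 s cycle, so a per-cycle
reading is arithmetically impossible; cumulative-over-window is the only
consistent interpretation, with `per_cycle_mean` exposed as an option.

**Circular phase and R.** The circular time of a limb is its swing
duration, lift-off → next same-limb touchdown, following the published
description of the interval ("from when the hind-limb lifted off and
touched down again"); R is the right/left ratio of the window means. Raw R
is always reported; cohort-level sham normalization (dividing by the sham
cohort's mean raw R, making the sham mean exactly 1) is available, which is
how "mean R normalized to 1" is interpreted here.

**Ankle pattern.** The SNL ankle rises slowly over the first two thirds of
swing and fast over the last third. Marker-speed angles are not defined by
the source, so the pattern is operationalized as the ratio of least-squares
slopes of ankle height against normalized swing phase on u ∈ [0, 2/3] and
[2/3, 1]. The early slope is clipped below at 1e-6 (with a warning) to keep
the ratio finite on flat early swings.

**Statistics.** Paired t (closed form, df = n−1) for left-vs-right within
SNL and weekly von Frey comparisons; Mann–Whitney U with midranks for
SNL-vs-sham. The exact U distribution is used for tie-free samples up to
n = 20; with ties and small n the exact conditional permutation
distribution is enumerated; otherwise a normal approximation with tie and
continuity corrections. Two-sided everywhere, α = 0.05, no multiplicity
correction by default (a Holm option exists) — matching the per-metric
reporting convention of the assay.

**Allodynia.** The probe ramps 1→50 g over 20 s; thresholds are recorded
as times and all statistics stay on the time axis (the gram conversion is a
labeled convenience, since the published figure reports threshold *time*).
Three trials per paw are averaged; the percent decrease is
`100·(right − left)/right` per animal-week; the overall "weeks 1–8" value
is the mean of weekly cohort means (weeks equally weighted — the source
does not state its pooling; per-animal pooling is a small code change).
The 95% CI is `mean ± 1.96 · sd(weekly means)/√8`. This reading is
self-consistent: a weekly cohort-mean SE of ~6 points gives a CI of width
~8 points around 47%, as published; treating 6.1 as the SE of the overall
mean would give a CI twice as wide as the published one.

## The synthetic cohort generator

The generator is a stated world, not a tuning knob: its defaults are the
published group summaries, and tests are parameter-recovery exercises
against it.

**Timing.** Left touchdowns every `T = 0.64 s` (stride 12.8 cm at
20 cm/s); the right touchdown falls `(1 − φ)·T` after the left, where φ is
the left-step fraction of the stride (sham 0.5; SNL week 1 8.1/12.8 ≈
0.633; week 4 8.2/12.8). Duty factors (stance fraction, constrained to the
walking range (0.5, 0.9)) are *calibrated*, not guessed: given a both-foot
contact target over the 10-stride window and a right/left swing ratio
(the R target), the windowed stance overlap is an analytic function of the
duties (interval arithmetic on the unit circle), and a 1-D root solve
yields the pair. For the defaults: sham wk4 d = 0.5805 both sides; SNL wk1
d_L = 0.5858, d_R = 0.7267; SNL wk4 d_L = 0.5660, d_R = 0.7309. A
brute-force dense-grid overlap counter verifies the calibration in the
test suite.

**Waveforms.** Hip/knee/iliac: flat stance, single smooth swing bump
(`sin²`), plus — in SNL presets — a dip below the stance baseline active
only in the second half of swing (the "downward after upward" instability
sign). The dip is a dimensionless shape weight (sham 0, SNL 0.8, ≈ 0.25·A
below baseline after normalization): because each cycle is
range-normalized, an absolute dip depth in cm would not be separately
identifiable. Ankle: piecewise-linear rise through swing with slopes s1,
s2 (sham 1:1; SNL 0.4:1.6 so the slope-ratio metric separates groups by
construction), settling back during stance; the knots are left sharp so
the fitted slope ratio is analytically the parameter ratio. Toe: on the
belt throughout stance, swing arc `√(sin π u)` with a 1.0 cm apex — the
steep edges mirror the impulsive toe-off/landing of real gait and keep the
0.15 cm threshold crossing within ~2 ms of the true event. Foot x is
anchored so every touchdown lands at the same lab x; the stance foot rides
backward with the belt, making the walker exactly stationary on average.

**Range normalization.** Every sampled cycle of every marker is rescaled
so its sampled `max − min` equals the amplitude parameter *exactly*. This
is the contract that lets the fluctuation metric be tested to 1e-6 on
noiseless data at finite (100 Hz) sampling; without it, sampling the
analytic waveform would undershoot the true range by O((Δu)²) ≈ 0.003 cm.
At the default T (64 frames per cycle) all cycles are frame-aligned, so
the normalization introduces no cycle-to-cycle waveform differences.

**Between-animal variation.** Printed summaries are mean ± SE with n = 10,
so per-animal parameters are drawn as independent normals with
SD = SE·√10, truncated by rejection to a window *symmetric about the mean*
(the asymmetric "valid range" truncation would otherwise bias the
calibrated means). Per-animal draws and noise streams are deterministic
substreams of the cohort seed. Marker noise is additive Gaussian, default
0.05 cm. Sham amplitude SDs reuse the SNL SEs (none are printed for sham).
Variation in both-foot contact and R is realized by re-calibrating each
animal's duty factors to its drawn targets.

**Parameters not stated anywhere** (chosen once as field-plausible, then
frozen): sampling rate 100 Hz (resolves 0.17–0.28 s swings with 17–28
frames); nominal marker heights (hip 6.5, knee 4.5, ankle 2, iliac 8 cm);
toe swing apex 1.0 cm; σ(φ) = 0.02; intact-paw von Frey threshold 10 ± 1.5 s
with 0.5 s trial noise; 12 strides simulated per trial (window 10 plus
edge padding).

## What a green test establishes — and known limitations

- **Recovery tolerances are wide by design.** Group-mean checks use ±2 SE
  with the published SEs; with n = 10 and between-animal SDs of SE·√10 the
  cohort mean itself has SD = SE, so recovery tests are ~95% events per
  check, with pre-registered seeds. They validate calibration and absence
  of gross bias, not sub-SE accuracy.
- **Feasibility truncation biases R upward.** The published R SEs imply
  between-animal SDs of 0.47–0.63 around means of 0.62–0.66. Draws with a
  very low swing ratio are geometrically incompatible with the drawn
  both-foot contact target under walking duty factors (a short right swing
  forces a double-support floor above the target), and such (ratio, bfc)
  pairs are jointly redrawn. The surviving distribution loses part of its
  low-R tail, so recovered SNL cohort means sit ≈ 0.1–0.15 above the 0.62
  target (inside the ±0.30 acceptance band, and slightly inflating
  both-foot contact too). The published marginal SDs, the both-foot
  contact times and the walking-gait constraint cannot all hold jointly;
  real animals presumably correlate these quantities.
- **Printed step/stride SEs are over-determined.** One cycle period drives
  both limbs' strides, so left/right stride SEs of 0.9 vs 0.3 cannot both
  be generated; σ(T) follows the left value and step/stride recovery uses
  model-implied SEs.
- The generator emulates kinematic geometry, not dynamics: no mass,
  no ground-reaction forces, no lateral (y) gait content, noise white
  rather than tracking-correlated, and trials are strictly periodic aside
  from the parameter draws. Green tests therefore establish that the
  *pipeline measures what the model encodes*, not that the model exhausts
  real rat gait.
- Noise inflates per-cycle extrema: with 0.05 cm white noise and ~64
  frames per cycle, `max − min` is biased up by roughly 0.1–0.15 cm
  (extreme-value effect on the flat stance). The metric is left unsmoothed
  because the noiseless exactness contract takes precedence; the bias is
  well inside the recovery tolerances and would equally affect any
  max-minus-min instrument.
- C3D import is unavailable in this build (no R-side reader); the CSV
  dialect is canonical.

## Numerical details worth knowing

- Cycle membership uses half-open windows with a 1 ns guard shared by the
  generator and the metrics, so boundary frames are assigned identically
  on both sides of a comparison.
- Missing marker positions are linearly interpolated up to 5 consecutive
  frames; longer dropouts reject the trial rather than fabricate a swing.
- `to_belt_frame()` refuses to run twice (idempotence guard); metrics that
  need belt coordinates refuse lab-frame input.
- All CSV writers serialize at 15 significant digits; write–read round
  trips reproduce series to better than 1e-9 and are byte-stable, and the
  pipeline report is byte-identical for identical inputs and seed.
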