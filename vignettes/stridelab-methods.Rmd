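---
title: "Methods: stride-level analysis of hindlimb locomotor EMG and kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stride-level analysis of hindlimb locomotor EMG and kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Chronic treadmill experiments on rodent locomotion record two
synchronized streams per session: retro-reflective marker trajectories
(six skin landmarks — rostral and caudal pelvis, hip, knee, ankle, first
digit — at 200 Hz) and multi-channel intramuscular EMG (seven muscles at
5000 Hz). The scientific questions live at the level of the *stride*:
how much of each cycle is stance, how joint angles and their ranges of
motion change across weeks of adaptation, and how much each muscle's
stance-related burst grows or shrinks relative to its own pre-perturbation
baseline. `stridelab` implements the full chain from raw channels to those
stride-level features and to the mixed-effects contrasts that compare
them across weeks, together with a synthetic generator that makes every
stage testable against known ground truth.

## Signal conditioning

**EMG.** Raw channels are band-pass filtered at 5–500 Hz (4th-order
Butterworth) to strip motion artifact and out-of-band noise, full-wave
rectified, and smoothed into linear envelopes with a 20 Hz 4th-order
low-pass. All filtering is zero-phase (forward–backward), so burst
timing is not biased by filter delay. The band-pass is realized as a
cascade of a 4th-order high-pass at 5 Hz and a 4th-order low-pass at
500 Hz: an 8th-order direct-form band-pass with a normalized low corner
of 0.002 is numerically fragile in transfer-function form, whereas the
cascade is stable and has the product magnitude response. For long
records the zero-phase pass is applied spectrally — multiplication by the
cascade's $|H(\omega)|^2$ with odd-reflection padding — which is the exact
transfer function of a forward–backward pass and several times faster
than time-domain filtering; short segments use time-domain
forward–backward filtering with reflection padding and DC-offset
correction. The envelope smoother choice (low-pass of the rectified
signal, rather than RMS or Hilbert magnitude) is conventional in
locomotor EMG and is configurable (`envelope_lowpass_hz`,
`envelope_filter_order`).

**Markers.** Trajectories are low-pass filtered at 10 Hz (5th-order
Butterworth, zero-phase). Masked samples (occlusions) are never invented:
runs of at most `gap_interp_frames` (5 frames, 25 ms) are bridged
linearly *only* so the filter sees a continuous series and are re-masked
afterwards; they still count as missing for the stride-exclusion rule.
Longer runs stay missing and each contiguous valid segment is filtered
independently.

## Kinematics

Angles are computed on the sagittal plane (x along the belt, rostral
positive; y up; the lateral z coordinate is dropped). Because the knee
skin marker slides over the joint during flexion, the knee is
*reconstructed* rather than measured: it is the intersection of a circle
of radius `femur_length` around the hip with a circle of radius
`tibia_length` around the ankle. Of the two intersections the anatomical
branch is kept — with the axis conventions above, the knee lies on the
anterior side of the hip–ankle line, i.e. the signed area of
hip → ankle → knee is positive; the convention is fixed per subject in
`limb_geometry()`. When noise pushes the hip–ankle distance outside
$[\,|f-t|,\ f+t\,]$ no intersection exists; the closest point on the
hip–ankle line that splits the residual equally between the two length
constraints is returned and the frame is flagged infeasible. Flagged
frames count as missing for the exclusion rule, so the stride screen
remains the single gatekeeper.

Joint angles are unsigned angles in degrees with 0° = complete flexion
and growing values = extension: hip between hip→rostral-pelvis and
hip→knee; knee between knee→hip and knee→ankle; ankle between knee and
toe directions at the ankle. Two global summaries complement them: the
limb vector hip→toe (its length, mm) and the limb angle between the limb
vector and hip→rostral-pelvis. The hip and limb angles share the
rostral-pelvis anchor so that the local and global descriptions are
mutually consistent.

**Stance.** On a treadmill the stance signature is the toe moving *with*
the belt: its forward velocity is close to minus the belt speed, while in
swing it moves forward. Foot-strike is the downward crossing of the toe's
forward velocity below `-stance_frac_threshold ×` belt speed (default
0.5) and foot-off the reverse crossing. Intervals shorter than
`stance_min_s` (50 ms) are dropped and intervals separated by less than
three times that (150 ms, far below any credible swing) are merged, so
occlusion-bridging blips cannot split a stance in two. The method is
marker-only and configurable because gait events could equally be defined
from other signals.

## Strides

The stride fiducial is the onset of tibialis anterior (TA) activity. The
onset detector thresholds the envelope at quiet-floor mean + `k_sd`
standard deviations, where the quiet floor is the set of samples at or
below the `onset_quiet_quantile` quantile, with two robustness
constraints: a crossing must stay supra-threshold for `onset_min_burst_s`
(50 ms) and successive onsets must be `onset_min_gap_s` (150 ms) apart.
Because the lowest-decile statistic can land inside the slow fluctuations
of the smoothed noise floor, the threshold is additionally floored at
`onset_min_level_frac` (5%) of the envelope's 95th percentile. Every
ingredient is a quantile or moment of the data, so onset times are
invariant to electrode gain.

Each stride spans one TA onset to the next (the last onset opens no
stride). Three single-pass screens then flag — never delete — strides:

1. **duration_outlier** — duration further than 1.5 sample standard
   deviations (n − 1 denominator) from the session mean, both computed
   once over all segmented strides of the session;
2. **emg_artifact** — for any muscle, the stride's envelope maximum
   exceeds the Tukey fence Q3 + 1.5 · IQR of that muscle's per-stride
   maxima (quartiles by linear interpolation of order statistics, R
   type 7) — the signature of cable-strike transients, which hit channels
   unpredictably;
3. **kinematic_missing** — any kinematic channel missing in strictly more
   than 20% of the stride's frames (reconstruction-infeasible knee frames
   included).

Statistics are computed once per session and not re-applied iteratively,
so screening is idempotent. An optional "stable walking" screen
(`min_bout_strides`: only runs of at least that many consecutive
duration-passing strides) exists but is off by default. Included strides
are time-normalized to 100 samples by linear interpolation across
`[start, end)`; masked samples are interpolated only when flanked by
valid neighbours (single-frame gaps), otherwise they propagate.

## Features

Per included stride: stance percentage (stance duration / stride
duration × 100); per-joint range of motion (max − min over valid raw
frames); joint angles and the two limb features at the *end of stance*
(the normalized sample at foot-off) and at *mid-burst* (the midpoint of
the detected quadriceps extension-burst window, an earlier point within
the stance-related burst; the anchor muscle is `burst_muscle`, default
RF). The integrated extension burst is the trapezoidal integral of the
envelope over the supra-threshold burst window inside
`[stride start, foot-off]`, at the native EMG rate so the result is in
mV·s regardless of time normalization; if no supra-threshold burst is
found, a stance-anchored fallback window
`[foot-strike − 0.1 · duration, foot-off]` is used. Raw integrals are
divided by the subject's mean baseline-week integral for the same muscle,
giving the relative change of activation; baseline strides therefore
average to exactly 1 and electrode gain cancels. Subjects without
baseline strides for a muscle contribute no normalized rows for it.

## Statistics

Each kinematic feature is modelled as
`value ~ week + (1 + week_numeric | subject)` by REML, with `week`
categorical (baseline reference) and `week_numeric` the elapsed weeks
(0, 1, 2, 7) carrying the by-subject random slope. The two-muscle EMG
model is `log(value) ~ week * muscle + (1 + week_numeric | subject) +
(1 | session within subject)`: the log symmetrizes the multiplicative
features, and the session intercept captures the nesting of strides
within each subject and recording day. Singular or non-converged fits
fall back along a recorded ladder (drop the subject slope, then the
session level); small-N designs make boundary estimates common and the
downgrade is reported in the fit object and `glance()`.

Hypotheses are Wald t contrasts on the fixed effects with Satterthwaite
degrees of freedom, Bonferroni-corrected: each raw p is multiplied by the
family size and capped at 1 (corrected p-values of exactly 1 are
expected). Families follow the questions asked: per kinematic feature the
three week-versus-baseline contrasts; for the EMG model the pooled family
of per-muscle week-versus-baseline contrasts plus the muscle difference
at each post-lesion week (9 for a four-week design). Whether kinematic
families should instead be pooled across features is not settled by
convention; per-feature is the default and documented here. Paired
ipsilateral/contralateral muscle masses are compared with two-sided
paired t-tests, Bonferroni-corrected across the muscles tested. Residual
and random-effect diagnostics for qq-plots are exported by
`export_diagnostics()` / `autoplot()`.

## The synthetic generator

`gait_scenario()` / `generate_experiment()` emulate the recording
sessions so that every stage above can be checked against ground truth.
The limb is built from an endpoint path rather than from angle
templates: during stance the ankle travels rearward at belt speed at
constant height; during swing it returns along a smooth profile with zero
end-point velocity and a lift; the foot direction is constant in stance
and rotates during swing. The knee then follows *exactly* from the
segment lengths (anterior circle-intersection branch), so artifact-free
markers lie on the true kinematic chain to machine precision — which is
what the triangulation and forward/inverse-kinematics oracles require.
Joint-angle ground truth is computed from this noise-free chain.

EMG channels are band-limited (30–450 Hz) Gaussian carriers of unit RMS
multiplied by a deterministic amplitude envelope: a small tonic floor
plus one cosine burst per stride between muscle-specific cycle fractions,
scaled by the per-muscle, per-week gain. The expected rectified envelope
is $\sqrt{2/\pi}$ times the amplitude envelope and the burst integral is
`amp · gain · width / 2` for any attack fraction, so integrated-burst
recovery has a closed form. TA uses a fast attack (12% of the burst)
because its onset is the stride fiducial; a zero-slope onset is both
physiologically implausible and undetectable with millisecond precision.
Residual 60 Hz line interference, sparse large cable-strike transients,
Gaussian marker noise, a stride-locked low-frequency skin-movement
displacement added to the knee marker only (the channel triangulation
replaces), and random occlusion runs complete the corruption model.
Carriers are synthesized spectrally (shaped complex-Gaussian spectra),
which is both exact for a stationary band-limited Gaussian process and
fast.

**Default conditions.** Six subjects; weeks `base`, `week1`, `week2`,
`week7`; 78 true strides per session (screening then leaves roughly
55–65, the order of magnitude typical for such sessions); stride duration
0.70 ± 0.05 s; stance fraction 0.62 ± 0.015; belt 12 m/min; femur 38 mm,
tibia 42 mm, foot 20 mm. The adaptation pattern: VL gain collapses to
0.05 after the lesion (residual cross-talk); RF is strongly elevated
(2.6, 2.2, 1.9 at weeks 1, 2, 7); VM stays near baseline (1.04, 1.02,
1.00); stance fraction drops 8 points at week 1 and recovers fully by
week 7; limb excursion scales by 0.75 / 0.90 / 1.00; the ankle swing
amplitude transiently increases. Between-subject, between-session and
stride-level variability are log-normal with SDs chosen so that
subject-mean recovered gains have a standard error of a few percent —
variability large enough to exercise the mixed models, small enough that
six subjects remain informative. These values are the package's fixed
reference conditions, labelled synthetic throughout; they are plausible
for rodent treadmill locomotion but are not estimates of any particular
data set.

**What the generator does not emulate.** Real marker noise is neither
white nor stationary; skin artifact is not a clean stride-locked
sinusoid; EMG is not a modulated Gaussian (motor-unit structure, cross
talk between deep muscles, electrode drift are absent); stance onset in
real animals is a force event, not a velocity threshold; and durations
are not truncated-normal i.i.d. Passing tests therefore demonstrate that
the *pipeline* is correct and well calibrated under a controlled model of
the acquisition, not that any particular biological result would
replicate.

## Numerical choices and degenerate inputs

- Quartiles: linear interpolation of order statistics (R type 7), pinned
  for reproducibility of the Tukey fence.
- Sample SD uses the n − 1 denominator.
- Fewer than three strides per session: the two statistical screens are
  skipped with a warning; fewer than two TA onsets: empty ledger with a
  warning.
- Triangulation with coincident hip and ankle: infeasible flag if the
  segment lengths differ, an error (the solution set is a circle) if they
  are equal.
- Constant responses (e.g. an all-ones feature after log transform)
  cannot support variance components; the fit falls back to ordinary
  least squares on the fixed part with the downgrade recorded, and all
  estimates are zero.
- Natural log for the EMG transform (the base only rescales estimates).
- Problem sizes used by the test-suite simulations: Monte-Carlo
  calibration uses 200 replicates of 6 subjects × 2 weeks × 50 strides
  per cell at the feature level; gain recovery runs the full signal
  pipeline at 6 subjects × 2 weeks × 50 strides; the end-to-end
  adaptation check runs the default scenario across 10 seeds. These sizes
  give binomial/Monte-Carlo error well below the margins being asserted
  while keeping a full run on a single CPU practical.

## Known limitations

Stance timing from the toe-velocity criterion is biased late by roughly
10 ms (threshold crossing of a smoothed velocity step), and an occlusion
bridged across foot-strike can delay the detected strike by up to the
gap length; both are immaterial for stance-percentage contrasts but
matter if absolute event times are the target. The knee reconstruction
is planar; out-of-sagittal motion beyond a constant lateral offset is not
modelled. The EMG model compares only within-muscle normalized activity —
raw amplitudes are confounded by electrode gain by design. P-values from
small six-subject designs rest on Satterthwaite approximations; the
Monte-Carlo calibration suite is the evidence that they are honest under
the generator's conditions.
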