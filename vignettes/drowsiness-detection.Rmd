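---
title: "Multi-index drowsiness detection: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-index drowsiness detection: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perclos)
```

## The detection model

`perclos` treats drowsiness monitoring as a per-frame scoring problem
followed by a temporal decision problem. Each frame of a 68-point facial
landmark stream yields five indicators:

* **EAR**, the eye aspect ratio, from each eye's 6-point contour; the frame
  value is the arithmetic mean of the two eyes. Averaging was chosen over a
  per-eye rule because it is robust to single-eye landmark jitter and the
  two eyes close together in normal blinking and drowsiness; a wink biases
  the mean by at most half the single-eye drop.
* **MAR**, the mouth aspect ratio over the inner-lip ring. The inner
  contour is preferred to the outer because it closes completely — a shut
  mouth gives MAR exactly 0 — and needs fewer points. The default numerator
  pairs the three non-corner upper points with their opposing lower points
  (`‖p2−p8‖ + ‖p3−p7‖ + ‖p4−p6‖`). An alternative "printed" variant that
  measures the last pair against the mouth corner (`‖p4−p5‖`) appears in
  parts of the literature; it breaks the symmetry of the construction and
  no longer vanishes for a closed mouth, so it is available as
  `mar_variant = "printed"` but is not the default.
* **Gaze score**, the pupil's offset from the eye centre normalised by eye
  width. The eye centre is defined as the midpoint of the two *corners*,
  not the centroid of all six points: the corners do not move during a
  blink, so gaze remains well defined mid-blink.
* **Head pose** as yaw/pitch/roll Euler angles, by solving a
  perspective-n-point (PnP) problem between six rigid landmarks (nose tip,
  chin, outer eye corners, mouth corners) and a generic millimetre-scale
  3-D head model. Six points are enough for a well-conditioned pose and all
  six are insensitive to expression (lids and inner lips deform; these do
  not).

All three ratio indices are invariant under translation, rotation and
uniform scaling of the image — the property tests assert this over random
similarity transforms — so none of them needs camera calibration. Head pose
does: with no calibration available, the standard approximation
focal length = image width, principal point = image centre is used
(`camera_for_image()`), and both are overridable.

### Personalised thresholds

Eye and mouth apertures vary strongly between subjects, so fixed thresholds
misfire. The initialisation routine averages EAR and MAR over the first 5 s
of a session, during which the subject is asked to hold the mouth open,
and sets

* `EAR_thresh = 0.75 × EAR_mean` — eyes "closed" below 75 % of the
  subject's relaxed aperture;
* `MAR_thresh = 0.5 × MAR_mean` — mouth "wide open" above half the
  subject's maximal opening; when the mouth is never opened during the
  window (observed MAR never above 0.35) the population default
  `MAR_thresh = 0.35` is used and flagged (`mar_from_default`).

The same 5 s window serves both indices; only the mouth instruction needs
it, but using one window keeps the routine short and the EAR mean is
insensitive to window length on a compliant subject. Blinks during
calibration are *not* excised — the threshold is defined from the plain
average — so a calibration window dense with blinks lowers `EAR_thresh`
slightly; users needing tighter control can call `compute_thresholds()`
with curated means.

### The temporal evaluator

Five level-triggered alarms are evaluated per frame, with time measured on
the frame grid (`frame index × 1/fps`) rather than wall clock so that
logged streams replay bit-identically:

| alarm | condition | time limit |
|---|---|---|
| asleep | EAR < `EAR_thresh` | 3 s |
| yawning | MAR > `MAR_thresh` | 3 s |
| distracted | \|yaw\| > 30° or \|roll\| > 20° or \|pitch\| > 180° | 6 s |
| gaze_distracted | gaze > 0.4 while not `distracted` | 4 s |
| drowsy | latest completed 1-min PERCLOS > 20 % | — |

Comparisons are strict, matching the "below"/"above"/"more than" wording of
the rules. A condition must hold *continuously*: the alarm raises when
`t − run_start ≥ time limit` (so a condition starting exactly at 10 s
raises its 3 s alarm exactly at 13 s), clears the moment the condition
breaks, and re-raising requires a fresh run. Frames with failed validity
flags (no face, no pupils, degenerate pose) **break** runs rather than
extend them — missing data never creates an alarm. The gaze alarm is gated
on a currently non-distracted head: it specifically captures "head forward,
eyes elsewhere", and without the gate every sustained head turn would drag
a spurious gaze alarm along with it.

With the default `pitch_thresh = 180°` the pitch axis can never trigger
`distracted` (|pitch| ≤ 180 by construction); the default set deliberately
keeps the axis inert, and the test suite asserts this consequence. Lower
the limit (e.g. to 20°) to activate nod detection.

### PERCLOS accumulation

PERCLOS windows are anchored at the session origin and advance by exactly
one period (60 s) on completion, so there is no drift; the frame that
completes a window is counted in the next one. Each completed window emits
`closed frames × Δt / 60 × 100` %, where a frame is "closed" when its EAR
is below the calibrated threshold; the per-window scores are property-tested
against a brute-force recount. The global PERCLOS is the mean of completed
windows; a partial final window is reported separately
(`report$perclos$partial`) and excluded from the average, since a
30 s tail with one blink would otherwise dilute the session statistic. The
`drowsy` flag follows the most recent *completed* window: it raises at the
window boundary where the 20 % limit was exceeded and holds until a clean
window completes.

## The synthetic generator and what passing tests show

`render_stream()` deforms a fixed neutral template according to an event
schedule: eye events scale the projected vertical lid separations by
`(1 − magnitude)` so frame EAR is exactly `(1 − magnitude) × 0.30`; yawns
rescale the inner-lip separations to hit a target MAR to machine precision;
head turns rotate the 3-D layout and re-project; gaze events write pupil
centres at a chosen fraction of the eye width. The template has neutral
EAR 0.30 and neutral MAR 0.10, inside the ranges observed on alert
subjects, and its eye and inner-lip points each live on a constant-depth
plane so that perspective projection preserves their aspect ratios exactly.
The head sits 450 mm from a 640-px-focal camera — a typical dashboard
mounting distance — giving a ~55 px eye, large enough that sub-pixel
landmark jitter does not graze the decision boundaries.

`expected_alarms()` derives the alarm set a schedule must produce *without
rendering anything*: per-frame boolean conditions follow analytically from
the event definitions, and the sustained-run, gaze-gating and window rules
are applied to those series in an independent code path. The central
property — asserted over 200 seeded random schedules — is that the full
engine (render → score → calibrate → evaluate) reproduces this oracle
exactly in kind, count and onset (± one frame period), and stays exact
under Gaussian landmark jitter of σ ≤ 0.5 px.

What this does **not** show: the generator produces rectangular,
noise-free events with magnitudes drawn clear of the decision thresholds,
landmarks that never fail, and a rigid face. Real footage has gradual lid
droop, landmark-predictor bias that varies with pose and illumination,
occlusions (hands, sunglasses), and correlated — not i.i.d. Gaussian —
landmark errors. Passing the oracle suite validates the *decision logic and
geometry*, not landmark-predictor accuracy; deploying on real video stands
or falls with the injected detector and predictor backends. For the same
reason eye events and head turns never overlap in the random schedules:
under a rotated projection the closed-form EAR of a blink is no longer
`(1 − m) × 0.30`, so the oracle would have to render to know it — exactly
what an oracle must not do.

## Numerical choices

* **PnP** is solved by Levenberg–Marquardt (`minpack.lm::nls.lm`)
  minimisation of reprojection error over (yaw, pitch, roll, tx, ty, tz),
  initialised geometrically: tz from the ratio of model to observed
  outer-eye distance, translation from the anchor centroid, angles at zero.
  When a warm start from the previous frame is available both starts are
  tried and the lower-residual fit kept; warm-start angles below 1e-4° are
  snapped to exactly zero because MINPACK's relative finite-difference step
  underflows on tiny nonzero parameters and would freeze the coordinate.
  A fit whose RMS reprojection error exceeds 5 % of the anchor spread, or
  anchors with no spread at all (degenerate/coplanar input), yields
  `valid_pose = FALSE` instead of a pose. Batch scoring caches solutions by
  anchor configuration, so static-head runs cost one solve.
* **Euler convention**: intrinsic rotations applied yaw → pitch → roll
  about image-aligned axes (x right, y down, z into the scene),
  `R = Rz(roll) Rx(pitch) Ry(yaw)`, degrees, each angle in (−180, 180].
  Gimbal lock sits at |pitch| = 90°, far outside the monitored range.
* **Pupil detection** is a gradient-voting circular Hough transform: after
  a 3×3 box blur, edge pixels (gradient magnitude > 0.05 intensity/px)
  vote one radius inward against the gradient (pupils are darker than
  sclera); candidate radii span 10–40 % of the patch's smaller dimension; a
  candidate must collect at least 35 % of its ideal circumference votes
  (`pupil_config()`). The winning cell is refined by a darkness-weighted
  centroid, which brings localisation on rendered fixtures below 0.3 px.
  No vote above threshold means "no pupil", a valid outcome.
* **Bilateral filter** defaults (window 5×5, σ_space 2 px, σ_range 0.1 on
  normalised intensities) smooth sensor noise while leaving step edges in
  place; preprocessing exists for the pluggable detectors, not for the
  landmark arithmetic.
* **Degenerate frames** (zero eye/mouth width, collapsed anchors) set
  validity flags instead of raising: one bad frame must never abort a
  session. Direct calls to the low-level geometry (`compute_ear()` etc.)
  *do* raise classed errors, since silent NaN there would hide caller bugs.
* **Ties and boundaries**: all index comparisons are strict; the frame
  completing a PERCLOS window belongs to the next window; `run_start`
  comparisons carry a 1e-9 s tolerance so binary-representable frame grids
  (fps = 4) behave exactly.

## Problem sizes

The shipped tests use 4 fps streams (the package's target frame-rate
regime, where each frame is 0.25 s), sessions of 60–150 s, 200 random
schedules for the oracle-equivalence property, 1000 random similarity
transforms and 100 random rotations for the geometry properties; the whole
suite runs in well under a minute on one core. These sizes were chosen as
the smallest that exercise every window boundary and alarm interaction
multiple times; nothing in the engine depends on them.

## Known limitations

* No face detector or landmark predictor ships with the package; the
  front-end is a contract (`detect_face()`, `predict_landmarks()`) with
  injectable backends, and the HOG-primary/cascade-fallback policy is
  exercised with stubs. Video container decoding is likewise out of scope;
  use the landmark-stream formats or an image directory.
* Head pose assumes a generic head; systematic anthropometric deviation
  from the model biases angles by a few degrees, which the 30°/20° limits
  tolerate but a 5° application would not.
* The gaze score is one-dimensional (offset magnitude); it flags
  off-centre gaze but not its direction.
* Calibration happens once per session; slow drift (camera slip, posture
  change) is not re-tracked.
* PERCLOS windows are slightly sensitive to the session origin: the same
  closures split across a window boundary can score differently. This is
  inherent to fixed-window PERCLOS, not to this implementation.
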