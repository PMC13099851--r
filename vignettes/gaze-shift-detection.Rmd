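---
title: "Detecting gaze shifts in mobile eye-tracking: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gaze shifts in mobile eye-tracking: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeshiftr)
```

## The problem

Head-mounted eye trackers record gaze while the observer walks, turns, and
looks around. Two signals result: eye-in-head gaze positions (here ~200 Hz,
in scene-camera pixel coordinates) and a scene video (~30 Hz) from the
head's viewpoint. The analysis task is binary: segment the recording into
*gaze shifts* (saccades, including the fast resetting phases of
vestibulo-ocular and optokinetic nystagmus) and *non-shifts* (fixations,
pursuit-like tracking, slow phases). What makes this hard outside the lab
is that the image is not a fixed reference: during head motion, a perfectly
"fixating" eye sweeps across the image, while a fast eye rotation may keep
gaze on the very same object.

`gazeshiftr` implements a rank-based probabilistic detector that combines
eye kinematics with scene-video patch matching, three classical
threshold-based baselines, a two-level F1 evaluation protocol, and a
synthetic recording generator with exact ground truth.

## The rank-based detector

### Eye kinematics

Velocity and acceleration are estimated by least-squares fitting a
second-order polynomial to the gaze positions inside a 40-ms window
centered on each sample (a Savitzky–Golay filter), independently per axis.
Two implementation details matter:

* **Fits use actual timestamps**, not sample indices: mobile trackers drop
  samples, and fitting against time makes the estimator exact on
  polynomial trajectories regardless of gaps.
* **Windows never cross blinks.** Each contiguous non-blink segment is
  processed on its own; near a segment edge the window shrinks
  symmetrically, and a sample whose shrunken window holds fewer than three
  points is marked invalid. Mirror-padding was rejected because it
  fabricates data across blink boundaries. Invalid samples receive
  probability 0 downstream — no kinematic evidence of a shift.

At 200 Hz the 40-ms window spans 9 samples; for other rates the window is
the odd sample count closest to 40 ms, because the underlying quantity is
a time span, not a sample count.

### Rank probabilities

Speeds and acceleration magnitudes are ranked separately over all valid
samples of the recording (rank 1 = slowest, N = fastest) and mapped through

$$p_m(t) = \left(\frac{\mathrm{rank}_m(t)}{N}\right)^{\alpha},\qquad
p_{eye}(t) = \max\{p_a(t), p_v(t)\},$$

with $\alpha$ solving $(1 - f)^\alpha = 0.5$ for a top fraction $f = 0.10$:
$\alpha = \ln 0.5 / \ln 0.9 \approx 6.58$. The calibration is exact: on
tie-free data, exactly $\lfloor fN \rfloor$ samples map strictly above 0.5.
$\alpha$ is recomputed from `top_fraction` rather than hard-coded so the
identity holds to machine precision and the fraction stays configurable.

Design choices:

* **Ranking scope is per recording.** Pooling across a dataset changes the
  absolute probabilities but not within-recording ordering; per-recording
  ranking keeps detection self-contained per input file. (Nothing prevents
  a user from concatenating recordings to emulate pooled ranking.)
* **Ties get mean fractional ranks**, so quantized position signals do not
  produce order-of-input artifacts.
* Blink and invalid samples are excluded from $N$ and get $p_{eye} = 0$.

### Scene probabilities

For each consecutive frame pair the detector asks whether the visual
content at gaze changed. A square patch with sides of about 15° of visual
angle is compared at three places: current gaze in the current frame,
previous gaze in the previous frame (the reference), and the location in
the current frame that best matches the reference patch, found by sliding
the patch across the frame and minimizing the squared RGB difference.

Two probabilities result. The first compares *excess* patch differences —
how much worse the patch at current (resp. previous) gaze matches the
reference than the best match does:

$$p_{scene,1} = \frac{d_{current}}{d_{current} + d_{previous}}.$$

The second is purely geometric: the distance from the current gaze to the
best match ("not tracking") against the distance from the previous gaze to
it ("image shift"):

$$p_{scene,2} = \frac{D(g(t), m(t))}{D(g(t), m(t)) + D(g(t-1), m(t))}.$$

They combine by geometric mean, as does the final fusion:
$p_{scene} = \sqrt{p_{scene,1}\, p_{scene,2}}$,
$p_{gaze} = \sqrt{p_{scene}\, p_{eye}}$. The geometric mean lets either
stream veto (a zero annihilates) while the fused value always lies between
the two inputs.

Numerical and design choices:

* **Patch difference is the mean (not the sum) of squared RGB differences**
  on the 0–255 scale. The probabilities are ratios of such values, so the
  constant factor cancels; the mean keeps values comparable when border
  clamping changes the effective patch.
* **Degenerate denominators.** $d_{current} + d_{previous} = 0$ (e.g. a
  static scene with unchanged gaze) gives $p_{scene,1} = 0.5$: no evidence
  either way. Both distances zero gives $p_{scene,2} = 0$: gaze coincides
  with the tracked patch, which is tracking.
* **Search policy.** The literal procedure slides the patch across the
  whole frame, which is `O(W·H·patch)` per pair. The default two-stage
  policy searches exhaustively on a 4×-block-averaged frame, keeps the
  four best well-separated coarse candidates, and refines each at full
  resolution within ±(8 + 4) px; the best refined candidate wins. Refining
  several coarse candidates (rather than one) protects against the coarse
  landscape being misleading on small or aliased frames. An
  `"exhaustive"` policy restores the literal full-grid search; on small
  frames the two-stage policy falls back to it automatically. Negative
  excess differences, which can only arise from a restricted search grid,
  are clamped at zero.
* **Ties break deterministically** to the smallest row, then smallest
  column, so detection is bit-reproducible.
* **Frame-pair-to-sample assignment** is a zero-order hold: the pair's
  probability applies to every 200-Hz sample in `(t_prev_frame,
  t_frame]`. Linear interpolation is available behind a flag, but the hold
  is the default because the pair measures a change *over that interval*.
* Pairs whose gaze is blinked (or missing) at either frame are
  unavailable; affected samples fall back to the eye-only probability and
  are flagged. With no scene at all the detector *is* the eye-only
  variant.

### Segmentation grammar

Samples with probability strictly above 0.5 are grouped into maximal
consecutive runs (never across blinks). Then:

1. **Direction pruning:** within a group, per-sample steps whose direction
   deviates by strictly more than 90° (shortest angular distance) from the
   group's overall displacement direction are removed, in a single pass,
   and the displacement is recomputed. A single pass guarantees
   termination; steps of zero length are never outliers. A group left with
   fewer than two samples is discarded.
2. **Amplitude filter:** groups whose endpoint-to-endpoint rotation does
   not strictly exceed 1° are dropped (a group at exactly 1.0° is
   dropped).
3. **Merge or discard:** scanning left to right, when the offset-to-onset
   gap between consecutive shifts is strictly below 50 ms, the two merge
   if their directions differ by strictly less than 45° (the merged event
   spans the gap; displacement is recomputed endpoint to endpoint);
   otherwise the shift with the smaller *amplitude* is discarded
   ("smaller" by amplitude, not duration, since amplitude is the quantity
   the pipeline already filters on). The scan re-examines after every
   change, so chains of three or more close events resolve
   deterministically, and a discarded event can unblock a later merge.
   Gaps containing blink samples are never merged or discarded across,
   preserving the invariant that no reported saccade overlaps a blink.

All boundary conventions are strict inequalities, matching the rules'
wording literally; the test suite pins each one.

## Baselines

* **I-DT** grows a window while the dispersion
  `D = [max(x) − min(x)] + [max(y) − min(y)]` stays within the threshold
  (default 22 px ≈ 1.7° at 13 px/°; minimum duration default 0 ms).
  Windows require at least two samples even with no duration threshold: a
  single point has dispersion 0 by construction and would make every
  sample open a "fixation", leaving nothing to call a saccade.
* **I-VT** thresholds raw sample-to-sample velocity (default 2 px/ms ≈
  150°/s at 13 px/°), attributed to the later sample; deliberately *not*
  the Savitzky–Golay velocity, to match the classical formulation.
* **Moving window** estimates velocities with a three-point parabola
  (equal to the central difference on uniform grids), then iterates a
  `mean + λ·SD` threshold (λ = 3.5) over windows of 6000 samples,
  removing exceeders until the threshold changes by less than a relative
  1e−6 ("stabilized" needs a tolerance; none is standard) or 50
  iterations. Fixations under 60 ms are then excluded and saccades under
  1° removed with their flanking fixations merged. The threshold
  iteration runs per window, matching the window-size semantics of the
  original toolbox. The saccade amplitude is measured from the sample
  before onset to the sample after offset, so the full jump is captured
  even though the parabola assigns peak velocities to interior samples.

## Evaluation protocol

Predictions and reference labels are compared on the recording's sample
grid after excluding the union of all blink samples (recording, predicted,
and reference blinks — the blink detector is not what is being evaluated).

* **Sample level:** per-sample binary confusion counts and
  `F1 = TP / (TP + (FP + FN)/2)`.
* **Event level (majority voting):** each reference saccade event is a TP
  if strictly more than half of its non-excluded samples are predicted
  saccade, else an FN. Each predicted saccade event is an FP unless
  strictly more than half of its samples fall in reference saccade
  regions. Exact 50/50 ties fail the "most frequent class" test on both
  sides (tie → FN for a reference event, FP for a predicted event). Events
  whose samples are all excluded are skipped.

This makes the event level deliberately lenient to boundary jitter: a
prediction shifted by a couple of samples still matches, which the
`jitter_boundaries` scenario demonstrates (event F1 = 1 while sample
F1 < 1). At the event level an over-segmenting detector can produce more
false-positive events than there are reference non-saccade intervals, so
the event-level FP *rate* may exceed 1; the rate is reported as-is.

## The synthetic generator: what it emulates, and what not

`scenario_config()` + `simulate_gaze()` produce a 200-Hz trace of
alternating fixations and saccades:

* **Saccades follow a minimum-jerk displacement profile**, which puts the
  velocity peak mid-movement and acceleration peaks at onset and offset —
  the premise behind taking `max(p_a, p_v)`.
* **Durations follow a main-sequence-like stand-in**,
  `duration = 20 + 2·amplitude` ms capped at 95 ms, keeping every
  simulated saccade under the 100-ms bound of classical main-sequence
  data. This is a fixture rule, not a physiological claim.
* **Fixations carry Gaussian jitter** (default SD 0.05°) and, under
  simulated head motion, ride a fixed scene location so the gaze point
  translates across the image like a VOR/OKN slow phase; saccade targets
  are chosen so the fast phases can undo the accumulated drift while gaze
  (and the 15° patch around it) stays inside the frame.
* **Blinks** blank the gaze, are labeled, never overlap saccades, and can
  displace gaze across the blink, as real recordings show.
* **Scene frames** (30 Hz) are seeded smoothed-noise textures translated
  per frame, with distinct high-contrast objects placed at the fixation
  anchors recovered from the trace itself, so the rendered video is
  exactly consistent with the gaze data.

Defaults are chosen once as a realistic stated world: 200-Hz/30-Hz rates;
13 px/° (the two conversions implied by common paired values, 22 px ≈ 1.7°
and 2 px/ms ≈ 150°/s, bracket it at ≈12.9 and ≈13.3); blink durations at
least the ~150-ms physiological minimum; scenario-specific amplitude
ranges documented in `make_benchmark_suite()`.

What the generator does **not** emulate: post-saccadic oscillations,
pupil-size-driven drift artifacts, photorealistic scenes, camera
distortion, illumination changes, or annotator disagreement beyond simple
boundary jitter. A green test on synthetic data therefore establishes that
an algorithm implements its specification and recovers events under its
own stated assumptions — not that it matches human labels on real outdoor
recordings.

## Degenerate inputs and conventions

* Intervals are half-open `[start, end)` in ms; a sample belongs to the
  interval containing its timestamp; densified gaps are non-saccade.
* Gaps between fixations recode as saccades when at most 100 ms and as
  blinks when longer (saccades in classical main-sequence data are
  shorter than 100 ms; blinks last at least ~150 ms). A gap of exactly
  100 ms is a saccade.
* Non-finite gaze positions force the blink flag on read.
* An all-blink recording yields zero saccade events (with a warning), not
  an error.
* All angular quantities use the small-angle linear conversion
  `px = deg × px_per_deg`; no camera model is assumed, and `px_per_deg`
  must be supplied for real data since scene-camera optics vary.
* Every source of randomness in the generator flows from one integer
  seed; identical seeds give bit-identical recordings.

## Known limitations

* Scene input is a PNG frame directory with a `frames.csv` sidecar (or
  in-memory arrays); video containers must be pre-extracted, as no video
  decoder is available in the supported dependency set.
* The binary scheme does not separate smooth pursuit, OKN or VOR slow
  phases from fixations; that is out of scope by design.
* Patch matching assumes the scene changes mostly by translation between
  consecutive frames (33 ms); strong rotation, zoom or motion blur will
  degrade the scene probabilities, which is why the fusion lets the eye
  stream carry pairs where scene evidence is unavailable.
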