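---
title: "Methods: head-gaze kinematics and hippocampal coding analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: head-gaze kinematics and hippocampal coding analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures the package implements,
the tunable parameters and their defaults, what the synthetic-session
generator does and does not emulate, and the numerical and design choices
made where the procedure left room. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Coordinate conventions and data model

All analyses consume a `session_bundle`: head pose at 60 Hz (3D position in
cm plus scalar-first unit quaternions), sorted spike times per unit, LFP
channels at 1 kHz, and a `maze_model`. The frame is right-handed with z up,
origin at the lowest south-west corner of the enclosure; yaw 0 faces +x,
pitch is positive upward. All intervals are half-open `[t0, t1)`, and all
time axes share one clock with `t = 0` at session start. Tracking gaps are
explicit missing samples: downstream operations skip them and never
interpolate (the conservative choice; fabricated kinematics would feed
every later stage).

The real maze's dimensions are not published. The default `maze_model()`
uses a 100 × 50 × 120 cm box with three floors and 12 wall ports, chosen so
viewing distances up to ~1 m occur; the place partition is a 7 × 4 grid per
floor (84 bins) and view bins are ~25 cm cells on the unwrapped inner
faces. Both partitions are configuration, not claims: the published bin
counts (84 place / 106 view) identify a preset scale, not a reproducible
geometry.

## Kinematics

Translation speed low-pass filters position at 4 Hz (zero-phase) before
differencing; angular head velocity is the quaternion geodesic
`θ = 2 arccos |⟨q_i, q_{i+1}⟩|` per Δt, which is insensitive to the q/−q
double cover and free of gimbal problems. Movement epochs are maximal
supra-threshold runs extended to the nearest local minima below
half-threshold on each side — the refinement is unspecified in the source
procedure, and half-threshold hysteresis is the standard saccade-detection
choice. Peak time on velocity plateaus takes the earliest sample.

Two threshold discrepancies exist between the narrative and procedural
descriptions (15 vs 16 cm/s; 16° vs 10°). The procedural values
(200 deg/s & 10° head; 16 cm/s & 30 cm body) are the defaults; all four are
`analysis_config()` entries.

Amplitude is the path-integrated angular distance over the epoch rather
than net displacement: for ballistic, monotone gaze shifts the two agree,
and the integral is the robust choice for curved body paths. Artifact
ceilings are 2000 deg/s and 300 cm/s.

The Naka–Rushton fitter works on log-scale parameters (enforcing
`R_max, n, K > 0`) with BFGS from a data-driven start
(`R_max₀ = max r − min r`, `b₀ = min r`, `K₀ = median x`, `n₀ = 2`) plus
jittered restarts, best residual wins. `R(K) = R_max/2 + b` and
`R(0) = b` are pinned by tests.

## Cell typing

The burst index compares the measured ISI histogram (1 ms bins) against a
rate-matched exponential prediction. The printed procedure normalizes both
distributions over 2–40 ms but sums 2–20 ms; this asymmetric recipe is
implemented exactly as stated. The predicted mass is bin-integrated
(`e^{−λt₀} − e^{−λt₁}`) by default; evaluating the density at bin centers
(the literal per-bin reading) is the `bi_predicted = "center"` alternative
— for hippocampal rates (λΔt ≪ 1) the two are numerically
indistinguishable. Classification is 2-means on per-feature standardized
(BI, mean rate); standardization is our addition (the features are on
incommensurate scales and unstandardized k-means would be rate-dominated),
and the higher-rate cluster is labeled interneuron. Duplicate resolution in
QC falls back to spike count when waveform SNR is unavailable, as it is for
synthetic bundles.

## Tuning and selectivity

View ("facing location") casts the head's forward axis from the tracked
position and takes the first intersection with the six inner faces. Rate
maps exclude bins with ≤ 3 independent visits (maximal contiguous dwells)
or < 200 ms occupancy, and the occupancy distribution `Pᵢ` is renormalized
over included bins. SIC nulls circularly shift spike times (minimum 1 s
from either end, so near-identity shifts never enter the null); the shuffle
preserves spike count exactly. Cell-level selectivity uses the 95th
percentile of 5000 shifts; per-bin fields use the Bonferroni-corrected
`1 − 0.05/L` per-bin rate percentile. The two published descriptions of the
cell-level criterion conflict (plain 95th percentile vs bin-corrected); the
plain percentile is the cell-level default and both are configurable.

Speed scores correlate the 250 ms-Gaussian-smoothed frame rate with TS or
AHV at 60 Hz; classification needs `r > 0.3` *and* exceedance of the 95th
percentile of 1000 rate-series shifts. Both criteria are kept separate in
the result object so either can be inspected.

## Encoding GAMs

Counts in tracking-locked frames are modeled as
`y ~ Poisson(exp(β₀ + Σ f_r(x_r)))` with mgcv P-splines and GCV-selected
smoothing. Design choices:

* Multi-dimensional variables enter as additive per-dimension smooths —
  place (x, y, z), view (2D chart), head direction (yaw, pitch, roll) —
  treated as one unit during selection. Yaw and roll use cyclic splines.
* View coordinates are mapped to a single unwrapped chart (walls unrolled
  along a perimeter axis, floor/ceiling stacked above) so that face
  identity is encoded in the coordinates; without this, additive smooths on
  per-face coordinates cannot represent a field on one face. The long
  perimeter axis gets twice the basis size of other dimensions.
* Predictors are taken at the frame midpoint, and kinematic regressors are
  averaged over the frame: sampling them at frame edges aliases the
  stop/locomotion structure into the residuals, which inflates
  cross-selection between behaviorally coupled variables.
* Explained deviance is `ED = 1 − D_fitted/D_null`. The printed formula
  simplifies to the complementary ratio `D_fitted/D_null`, which would be 0
  for a perfect fit and cannot be the quantity maximized during selection;
  it is assumed a typographical slip, and `ed_formula = "printed"`
  preserves the literal form.
* Forward selection gates each candidate on 100 circular shifts — of the
  spike counts for first-order models, of the candidate predictor alone
  for higher orders — at the Bonferroni-corrected 95th percentile, the
  correction scope being the candidates tested in the current iteration.
  Among significant candidates the highest normalized ED
  (real − mean shuffle) wins. Null fits reuse the real fit's smoothing
  parameters rather than re-running GCV: the null only has to calibrate
  the ED scale at the chosen flexibility, and this makes the gate ~5×
  faster. The stopping rule is purely the shuffle gate (no ED-increment
  floor).
* Cross-validation uses 5 contiguous equal-time folds ("stratified" by
  session time; occupancy stratification is not implemented). Per-fold R²
  is the squared Pearson correlation between predicted rate and held-out
  counts; the F-test uses the fold-mean R² with the held-out frame count
  as its sample size.

## Place decoding

Fixation trials are local AHV minima inside sub-threshold (< 200 deg/s)
runs, with 200 ms integration windows kept non-overlapping globally. The
six floor-half bins give candidate classes; the four with the most trials
are retained and each must reach 50 trials. The decoder is a linear
one-vs-one SVM (L2-regularized squared hinge, C = 1, features z-scored on
training folds) — no SVM package exists in the target environment, so the
primal is solved directly with BFGS; on trial counts of this size it
matches the usual linear OvO setup. Accuracy is the mean over 10
balanced-subsample repeats × 5 folds, never the best. When labels are
shuffled to estimate chance, a fresh permutation is drawn per repeat so
the mean estimates the chance level rather than one permutation's quirk.
Greedy ensembles stop at 20 units or when improvement over the last 3
sizes falls below 0.005.

## LFP analyses

The printed preprocessing ("250 Hz high-pass, then downsample to 1 kHz")
would alias away every band of interest; it is implemented as a 250 Hz
*low-pass* anti-aliasing filter (with `lfp_preserve_printed_filter = TRUE`
reproducing the literal text). Filtering is zero-phase by construction:
the magnitude-squared Butterworth response applied in the frequency
domain, which is exactly what forward-backward filtering computes, with
reflection padding against wrap-around. Artifact rejection band-passes
100–250 Hz, takes the analytic-signal envelope (0.2 s boxcar), z-scores
it, and masks ±100 ms around crossings of 4 z — with the added guard that
the excursion must be material on the signal's own scale (5% of its SD),
since the envelope of clean narrowband input is essentially flat and its
z-scores are meaningless.

The Morlet TFR uses 7-cycle wavelets at 1–30 Hz with 25 ms temporal
smoothing of power; the dB baseline is the aperiodic component of the
session-mean spectrum, obtained by an iterative robust log-log linear fit
that excludes positive (oscillatory) outliers — the dependency-free
equivalent of a specparam/FOOOF aperiodic fit. Theta phase is the
analytic-signal angle of the 4–10 Hz zero-phase band-pass (band edges from
the narrative description; the procedural text never states them). The
Rayleigh statistic `Z = nR̄²` uses the standard finite-n corrected p-value
and a numerically inverted critical value at p = 0.01.

Peri-movement modulation uses 8 × 50 ms bins over ±200 ms, with a
1000-permutation whole-session circular-shift null; "up" requires
exceeding both the at-bin and the across-window-maximum 97.5th
percentiles (mirrored at 2.5% for "down"), giving the max-statistic
correction its familywise control. The shuffle shifts the whole spike
train (matching "circular permutation of spike times") rather than
permuting within windows, and z-scored traces use session-wide rate
moments.

## The synthetic world

`gen_session()` generates the statistical structure the analyses assume,
not marmoset biomechanics. What it emulates:

* Alternating stop epochs (mean 6 s, exponential, truncated) and straight
  locomotion bouts between targets (50% reward ports, 50% random interior
  waypoints), peak speed uniform on 16–60 cm/s with a raised-cosine
  profile. Waypoint stops matter: with stops confined to 12 ports,
  place, view and head direction are so strongly coupled through behavior
  that no selection procedure could attribute tuning uniquely.
* Ballistic head-gaze shifts during stops at 2 Hz (a realistic primate
  gaze-shift rate; the source gives no number), amplitudes log-normal
  (median 25°) truncated to 10–90°, peak velocities from the
  Naka–Rushton main sequence (`R_max = 795, n = 2, K = 20, b = 50`) with
  10% multiplicative noise; 80% of shifts fall inside stops. Shifts are
  pure yaw rotations: at constant pitch the per-sample quaternion
  geodesic equals the yaw increment exactly, so injected amplitudes are
  recoverable without bias. Re-orientation at locomotion onsets ramps at
  150 deg/s — deliberately below the 200 deg/s detection threshold.
* Spikes are inhomogeneous Poisson with *additive* log-rate terms
  (per-dimension Gaussian bumps for place and view-chart coordinates, von
  Mises for yaw, saturating ramps for AHV/TS) — the model family the
  encoding GAM assumes, which is what "the generating variable set" must
  mean for an exact-recovery test. Pyramidal units get burst doublets
  (extra spike 2–8 ms after a parent) so cell typing is recoverable.
* LFP is 1/f² background plus theta (7 Hz) whose phase diffuses at
  3 rad/√s between events and jumps to a fixed value at each
  head-movement peak, with an amplitude transient decaying over 150 ms.
  Phase diffusion is essential: without it the oscillation is coherent
  forever and every sample is "phase-locked" to every event.

What it does not emulate: eye-in-head movements, limb kinematics,
occlusion patterns of real motion capture, non-Poisson spike history
(beyond doublets), theta harmonics, or cross-frequency structure. A green
recovery test therefore establishes that the pipeline recovers what it
assumes, at realistic scales — not that real marmoset data meet those
assumptions.

Defaults are session-scale (40 min, 204 pyramidal + 127 interneuron
units); tests and the analysis drivers pass smaller sizes explicitly and
say so where they do.

## Numerical choices and degenerate inputs

Quaternions with norm error ≤ 1e-3 pass unchanged, ≤ 1e-2 are
renormalized, beyond that the pose is rejected. Circular-shift minima (1 s
for spike shuffles, 5% of frames for GAM shuffles) keep near-identity
shifts out of every null. Permutation counts below 100 are refused for the
SIC test (the 95th percentile of fewer values is too unstable to name a
significance level). Empty selections, zero-unit bundles, all-excluded
rate maps and empty event lists are defined results or clear errors, never
silent NA propagation. k-means uses 25 restarts under a fixed seed;
degenerate clusterings (zero-variance features, empty clusters) leave all
units unclassified with a warning.

## Known limitations

* The view partition's bin count depends on the stand-in maze geometry;
  published counts are not reproducible from published information.
* The GAM gate's false-inclusion rate depends on how many shuffles
  estimate the null percentile; below ~50 shuffles the empirical 97.5th
  percentile is permissive enough to double the nominal rate. The default
  (100) is calibrated; scaled-down test configurations state their counts.
* Exact variable-set recovery is bounded by genuine behavioral coupling:
  view is a deterministic function of place and head direction, so
  residual cross-selection (measured at ~1 unit in 9 on the test fixture)
  is expected, not a defect of the gate.
* The decoder's pseudo-population pairing (trials matched within class for
  non-simultaneous units) is implemented but untested against real
  across-session data, which the package never sees.
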