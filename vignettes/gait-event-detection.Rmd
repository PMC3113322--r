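---
title: "Detecting gait events from an instrumented-sock strain signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gait events from an instrumented-sock strain signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsock)
```

## The problem

A piezo-resistive strain sensor knitted into a sock at the ankle changes its
electrical resistance as the ankle flexes, so its voltage trace during
walking carries the same salient features as the sagittal-plane ankle angle:
maxima around heel strike (HS) and toe off (TO), minima around heel lift
(HL) and in mid-swing.  If the three stance-phase events HL, TO and HS can
be read off this single textile channel, a sock could replace the
footswitches used to trigger functional electrical stimulation in foot-drop
gait assistance — without shoes, connecting wires, or per-step weight-shift
artifacts.

Two obstacles stand in the way.  First, the knitted structure is
viscoelastic: its baseline resistance drifts over successive stretches and
the resistance–strain relationship shows hysteresis, so the raw voltage is
not a clean angle surrogate.  Second, the waveform differs considerably
between individuals (sock fit moves the operating point on the
resistance–strain curve), so any detector needs per-subject calibration.

`gaitsock` implements the full retrospective pipeline: signal conditioning,
sensor-vs-kinematics similarity statistics, a five-parameter peak-plus-offset
event detector with automated calibration, and a train/test evaluation
protocol in % gait cycle — together with a synthetic cohort generator that
reproduces the documented statistical structure of the sensor, including
ground truth for every event, so the whole pipeline is testable end to end.

## Signal conditioning

Three primitives cover every conditioning step:

* **Zero-phase FFT high-/band-pass** (`fft_filter()`).  The transform is
  taken, every bin with |frequency| outside the pass band is zeroed (band
  edges inclusive), and the inverse transform is returned.  A 0.3 Hz
  high-pass removes the sensor's baseline drift while keeping the
  low-frequency content of walking; the detection pipeline uses the
  0.3–4 Hz band-pass, the upper edge suppressing measurement noise.
  Brick-wall masking with no tapering is the simplest faithful realisation
  of an "FFT filter"; its edge ringing is tolerable because every trial
  carries 0.5 s of padding around the analysed cycle, and inclusive band
  edges make results bit-stable.
* **Zero-lag Butterworth low-pass** (`butter_lowpass_zero_lag()`), used at
  6 Hz (order 4) on the ankle-angle channel before locating the HL trough.
  The design is a bilinear-transform Butterworth applied forward and
  backward, so the effective response is the squared magnitude with zero
  phase — peaks and troughs do not move.  Because no filtering package is
  available in the target environment, the design and the filtering loop
  are implemented here and were cross-checked against a reference
  implementation (coefficients and filtered output agree to ~1e-12).
* **Linear resampling** (`resample_linear()`) to bring the 100 Hz ankle
  channel onto the sensor's 1500 Hz grid, and **peak-to-peak scaling**
  (`scale_peak_to_peak()`), which is purely multiplicative: the band-pass
  has already removed the means, so matching ranges suffices to overlay the
  two signals.

Two numerical choices deserve a note.  Endpoint transients of the
forward-backward Butterworth are handled by odd-reflection padding with
steady-state initial conditions; the padding length scales with the filter
time constant (`3 * order * fs / cutoff` samples, capped by the signal
length) because a fixed handful of samples leaves startup transients that
visibly break the zero-phase (time-reversal) symmetry at the edges.  And
local extrema on plateaus of equal samples always resolve to the plateau's
first sample — deterministic and order-independent.

## Similarity statistics

Per gait cycle (heel strike to heel strike, half-open at the second heel
strike so it is not double counted), both channels are sliced, the ankle
channel upsampled to 1500 Hz, both band-passed at 0.3–4 Hz, and two
statistics computed:

* Pearson's correlation coefficient $r$;
* the normalised mean absolute deviation,
  $\mathrm{nMAD} = \frac{1}{n}\sum_i |\tilde v_i - \tilde\theta_i|$, where
  each signal has been scaled *multiplicatively* to unit peak-to-peak range.
  No offset is subtracted: the band-pass already removed the means, and the
  statistic is meant to compare variation irrespective of amplitude.

Per-subject values are arithmetic means over one cycle per trial.

## The event detector

Detection runs on the band-passed but *unscaled* voltage — the threshold
parameter is specified in volts — as a three-stage forward search from the
first heel strike:

1. find the first point $P_1$ where the signal is increasing and exceeds a
   threshold $a_1$; predict HL at $P_1 + a_2$;
2. find the first local maximum after $P_1$ (the toe-off peak); predict TO
   at that peak $+\,a_3$;
3. advance by $a_4 > 0$ (past the mid-swing trough) and find the next local
   maximum (the end-of-cycle peak); predict HS at that peak $+\,a_5$.

The four offsets $a_2, a_3, a_5$ (signed) and $a_4$ are fixed in seconds,
not in % gait cycle, so the detector never needs to know the cycle duration.
Offsets are typically negative for HL: the method deliberately locates
events *behind* the sensor features, which is why it is retrospective rather
than real-time.

**Calibration** (`calibrate()`) uses training trials with known events (the
first five of each subject/condition).  Per trial the toe-off peak (first
local maximum of the conditioned signal after true HL) and the end-of-cycle
peak (first local maximum within ±25% cycle of the true second heel strike)
are located.  The threshold $a_1$ is the mean over trials of the midpoint
between the *maximal signal value over the initial stages of the cycle*
(the interval from HS1 to HL, which contains the heel-strike peak) and the
toe-off peak value.  The floor must be the early-cycle maximum rather than
the HL trough value: any threshold below the heel-strike peak can fire
$P_1$ at the very start of the search whenever that peak crests just after
the force-plate heel-strike instant, which a midpoint anchored at the trough
cannot avoid.  The threshold is verified on every training trial ($P_1$
must land on the rising edge of that trial's toe-off peak) and lowered in
10% steps at most five times; if verification still fails, calibration is
declared infeasible.  This is exactly the observed failure mode when a
spurious peak of toe-off magnitude sits at ~30% gait cycle: the threshold
cannot simultaneously clear the spurious peak and stay below the toe-off
peak, and the subject's row is reported as dashes.  Finally $a_2, a_3, a_5$
are the mean signed offsets between true events and their anchors, and
$a_4$ is *half* the mean toe-off-peak-to-heel-strike-peak interval — late
enough to skip the mid-swing trough, early enough to stay before the
heel-strike peak under moderate jitter.

## Ground truth and evaluation

Ground truth never comes from generator metadata.  Heel strikes and toe off
are read from the two force-platform channels as the first/last samples
strictly above 5 N (first channel: HS1 and TO; second channel: HS2), and HL
is the last local minimum of the 6 Hz-filtered ankle angle within 0.5 s
before TO — the instant the ankle begins to plantarflex in preparation for
push-off.  The 0.5 s window covers terminal stance at normal cadence
without reaching back to earlier features.

`evaluate_subject()` calibrates on trials 1–5 and predicts on trials 6–10;
the signed error per event is $100\,(t_{true} - t_{pred})/(HS2 - HS1)$ in
% of that trial's own cycle duration (the natural reading when each trial
contributes exactly one cycle).  Reports carry the mean absolute error and
the SD of the signed error over the test trials; `cohort_table()` adds an
average row over subjects with feasible calibration, and rounding to one
decimal happens only at rendering.

## The synthetic cohort

No recordings are deposited, so the generator *is* the test bed.  It states
a world consistent with everything documented about the sensor:

* **Waveform**: a sum of signed asymmetric Gaussian bumps at
  HS1 (+), HL (−), TO (+), mid-swing (−), HS2 (+), placed at 0/40/60/80/100
  % of the cycle — standard normal-gait timing, since only the feature
  order and polarity are documented.  Gaussians give controllable,
  differentiable peaks.  Different rise and fall widths
  (fall = 0.72–0.90 × rise) emulate the viscoelastic hysteresis
  qualitatively without a full Preisach model.
* **Scales**: cycle duration per subject ~ Normal(1.1 s, 0.1 s) truncated
  above 0.6 s; sensor peak-to-peak ~ Uniform(0.2, 0.4) V, the documented
  range of the digitised voltage; ankle range 20–30°; GRF stance envelope a
  raised sine peaking at 1.2 body weight (arbitrary — only the 5 N
  crossings matter, and the boundary samples sit at 6 N so the crossing
  instants are exact grid times).
* **Nuisance structure**: linear drift (±0.02 V/s) plus a 0.05 Hz sine
  (≤0.03 V) for the baseline wander; white measurement noise at 5% of the
  subject's peak-to-peak; trial-to-trial timing jitter of each sensor
  feature around its true event (SD 10 ms sock-only, 15 ms shod) and the
  same jitter SD on the cycle duration.  The magnitudes of drift and noise
  are not reported anywhere in volts; they were chosen once so that the
  per-subject similarity statistics span the documented between-subject
  range (r roughly 0.3–0.9 across conditions) and were not revisited.
* **Sensor-vs-kinematics mismatch**: a per-subject coefficient
  $m \in [0,1]$ (drawn larger in the shod condition) engages amplitude
  perturbations of all features, phase shifts of the swing-phase features,
  and a slow additive distortion.  The HL trough is deliberately exempt:
  its phase is never shifted, its amplitude perturbation is mild, and the
  distortion is notched out around it, so the kinematic ground-truth
  definition stays well posed at any mismatch level (the generator
  guarantees recovery within one ankle sample).  True HL is snapped to the
  100 Hz ankle grid for the same reason; all other truth times live on the
  1500 Hz sensor grid.
* **Failure mode**: with probability 0.05 a shod subject gains a spurious
  positive peak at 30% gait cycle with 0.9–1.1 × the toe-off amplitude,
  reproducing the documented case where threshold calibration becomes
  infeasible.
* **Bench test**: `simulate_stretch_test()` emulates the characterisation
  experiment — triangle-wave strain at a set rate, resistance = linear gain
  × strain + decaying-exponential baseline drift + a velocity-proportional
  term (the hysteresis loop) + noise.  High-pass filtering at 0.3 Hz
  removes the drift and recovers a near-linear resistance–strain relation.

What the generator does **not** emulate: marker-based 3D kinematics and
their soft-tissue artifacts, the physics of stitch-contact resistance,
velocity-dependent resistance peaks beyond the first-order asymmetry term,
multi-step trials (each trial is one gait cycle with 0.5 s padding), and
pathological gait.  A green test suite therefore establishes that the
*pipeline* is correct and that its accuracy degrades gracefully with the
stated noise structure — not that the sensor itself meets any clinical
specification.

Reproducibility plumbing: every profile and trial derives its RNG stream
from the master seed and the subject/trial indices through a fixed integer
mixing function, so enlarging a cohort never reshuffles existing subjects,
and all draws run under a local RNG state that leaves the caller's
`.Random.seed` untouched.

## Open choices made here

* The exact form of the published automated threshold search is
  unspecified; the initial-stage-maximum midpoint rule with a bounded
  lowering fallback is this package's documented stand-in.
* Whether the detector ran on raw or 4 Hz-filtered voltage is ambiguous in
  the source material; the band-passed reading is the default
  (`detect_events(..., prepared = FALSE)` conditions internally), and
  `prepared = TRUE` lets callers supply their own conditioning.
* TO ground truth uses the symmetric GRF convention (last sample above
  5 N), and "exceeded 5 N" is read as strictly greater-than.
* %-gait-cycle normalisation uses each test trial's own cycle duration.
* The end-of-cycle calibration anchor is the first local maximum at or
  after HS2 − 25% cycle, erroring if it falls beyond HS2 + 25% cycle.

## Limitations

The detector is retrospective by construction (negative offsets place
events behind their anchor features) and is not a real-time trigger; the
calibration needs force plates and a motion-capture channel for its
training trials; and all accuracy figures produced by this package are
statements about the synthetic world above, at the stated noise levels —
they are computed fresh by the test suite and by `scripts/acceptance.R`,
never quoted.
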