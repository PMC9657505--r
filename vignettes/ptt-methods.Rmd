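---
title: "Methods: simulating and analyzing pulse transit time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing pulse transit time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pttkit)
```

## The measurement

Pulse transit time (PTT) is measured per cardiac cycle as the delay from
the ECG R-peak to a fiducial point on the photoplethysmogram (PPG) pulse
arriving at a peripheral site. `pttkit` uses the **maximum of the first
derivative of the systolic upstroke** as the PPG fiducial. This is the
standard choice for PTT work, and the best-conditioned one: the upstroke's
steepest point is far less sensitive to amplitude scaling and low-frequency
distortion than the pulse peak or foot. The alternative reading of
"inflection point" as the pulse foot differs from the max-slope point by an
approximately constant offset per morphology; since intervention analysis
works on *changes* in PTT, the choice shifts baselines but not conclusions.
It is configurable in spirit: the detector reports onset, inflection, peak
and dicrotic time per pulse, so a pipeline preferring the foot can pair on
`onset_s` instead of `inflection_s`.

PTT connects to vessel mechanics through the Moens–Korteweg pulse wave
velocity, `PWV = sqrt(E h / (rho D))`. Vasoconstriction decreases diameter
`D` and increases elastic modulus `E`, so PWV rises and PTT falls; this is
the sign convention used throughout (a constrictive event has negative
`delta`).

## The simulator and what it does (not) emulate

Every downstream stage is validated against synthetic recordings with fully
known ground truth. The generator works at 1 kHz by default, matching the
synchronous four-channel sample structure of the wearable data model the
binary format mirrors.

**Beat timeline.** RR intervals are `60/mean_hr` plus i.i.d. Gaussian
jitter plus event modulation, clipped at a 0.3 s refractory floor. The
first beat falls half a nominal interval after the start so boundary
complexes are never truncated; with zero jitter the beat count is exactly
`duration * mean_hr / 60`. The jitter is deliberately white: there is no
autocorrelated heart-rate-variability structure (no respiratory sinus
arrhythmia, no 1/f component). Consequently, SDNN/RMSSD tests validate the
*computation* of HRV metrics, not their physiological distribution.

**ECG.** One PQRST complex per beat, modelled as five Gaussian lobes with
the R maximum placed exactly on the beat time and an R amplitude that
strictly dominates the other lobes (defaults: P 0.12, Q −0.10, R 1.0,
S −0.15, T 0.30 in relative units). Gaussian lobes are not a morphological
claim — real QRS complexes are asymmetric — but they make every ground-truth
landmark analytic.

**PPG.** Each pulse is two Gaussian lobes: a systolic lobe (SD 40 ms) and a
smaller dicrotic lobe (amplitude ratio 0.25, SD 50 ms). For a Gaussian
upstroke the max-slope point sits exactly one SD before the lobe center, so
the simulator places the lobe center at `beat + PTT + sd_sys` and the
ground-truth inflection is analytic, not numerical. Pulse onset is defined
as the 1%-of-peak crossing, which for a Gaussian is `sqrt(2 log 100) ≈ 3.03`
SDs before the center; the defaults put the systolic peak 0.121 s and the
dicrotic peak 0.400 s after onset — inside the canonical morphology windows
of 0.10–0.15 s and 0.35–0.45 s used for validation. Overlapping pulses
superpose additively. The red and infrared channels are scaled copies of
the green channel with independent noise: no oxygen-saturation physiology
is modelled, which is why the toolkit deliberately offers no SpO₂
computation.

**Intervention events.** A `vaso_event` contributes
`delta * (1 − exp(−(t − t_on)/tau_on))` during the stimulus and relaxes as
`response(t_off) * exp(−(t − t_off)/tau_rec)` afterwards. Events are linear
(responses sum), continuous at `t_off`, and zero at their own onset. The
same structure modulates RR intervals, reflecting that heart rate and PTT
respond to the same stimuli with different time constants. A
single-exponential recovery is the minimal model consistent with an
observed "drop and recover" course; reported time constants are in seconds
and their physiological interpretation is left to the user.

**Noise.** Additive white Gaussian noise, a pure 50 Hz mains sinusoid,
sub-0.5 Hz sinusoidal baseline wander, and Poisson-placed Gaussian-shaped
transients (~0.5 s support) for motion artifacts. All draws derive from one
user seed through deterministic per-component sub-seeds, so a recording is
bit-reproducible given `(parameters, seed)`. Not emulated: electrode
contact changes, PPG morphology variability between beats, sensor
saturation.

## The binary container

Frames are packed as four 24-bit little-endian two's-complement counts
(12 bytes per 1 ms frame — 96 bits, which is what makes a 1 Gbit flash
worth `1e9 / 96000 ≈ 10417 s ≈ 2.9 h` of recording). Event markers are
stored as `(sample_index, code)` pairs rather than wall-clock times, tying
them unambiguously to samples; the header reserves two bytes for LED
time-slot metadata without populating them. Timestamps are integer
milliseconds since the Unix epoch, UTC, and default to zero so simulated
files are byte-identical across runs. Round-trip bit-exactness over random
recordings is part of the test suite.

## Conditioning choices

All multi-pass digital filters run forward–backward (zero phase). PTT is a
timing measurement: a causal filter's group delay would bias ECG and PPG
differently and show up directly as a PTT offset. Edges are reflect-padded
by about three filter time constants.

Defaults: ECG 0.5–40 Hz with a 50 Hz notch (Q = 30), PPG 0.3–15 Hz without
a notch. Two of these numbers deserve justification:

* **Notch Q = 30** gives a stop band under 2 Hz wide: ≥ 20 dB attenuation
  at 50 Hz while content 10 Hz away is altered by well under 3 dB.
* **PPG low-pass at 15 Hz**, above the usual perfusion band. A lower
  cutoff (e.g. 10 Hz) visibly broadens the Gaussian upstroke, and for a
  slope-maximum fiducial that broadening moves the detected inflection
  earlier by several milliseconds — a systematic bias, not noise. At 15 Hz
  the bias is below 0.5 ms while 50 Hz mains is still suppressed by more
  than 80 dB (4th-order Butterworth applied twice).

The first-order RC low-pass (`rc_lowpass`) models the device's analog
input stage via the bilinear transform with prewarping (exact −3 dB at the
cutoff, unit DC gain). It is causal by design — it emulates analog hardware
— and is not part of the default digital chain.

Artifact flagging is amplitude-based only (the data model has no
accelerometer): robust z-scores against a 10 s running median/MAD, padded
0.2 s per side. On conditioned ECG, clean QRS complexes themselves reach
robust z ≈ 30–35, because an R-peak *is* a sharp excursion against the
running median; transients of several times the QRS amplitude score well
above 45. The default threshold of 40 separates the regimes. The MAD is
floored at a tiny multiple of the signal scale to avoid division by zero on
idealized noise-free segments.

## Detection

**R-peaks** use the classic Pan–Tompkins cascade: 5–15 Hz band-pass
emphasis, differentiation, squaring, 150 ms moving-window integration, then
adaptive dual thresholds (running signal/noise level estimates) with a
0.2 s refractory period; within the refractory window the larger candidate
wins, which suppresses integration-ripple sidelobes. Each detection is then
refined to the local maximum of the conditioned ECG within ±50 ms, and
beats implying RR < 0.3 s are gated out (dropping the smaller peak). All
thresholds are relative, making detection invariant to positive rescaling.

**PPG fiducials** per pulse: systolic peak by local-maximum search (free
running with an adaptive relative threshold, or guided by R-peak times),
onset as the preceding minimum refined to the 1%-of-amplitude upcrossing
with linear interpolation, inflection as the upstroke's derivative maximum
refined by parabolic interpolation of the discrete derivative (sub-sample
precision — at 1 kHz the raw grid alone would limit PTT resolution to
1 ms), and the dicrotic wave as the most prominent local maximum within
0.5 s after the peak, bounded by the next pulse and reported as absent when
no candidate exists. Dicrotic detection is validation-only; PTT never
depends on it. Ties break toward the earlier sample; unresolvable pulses
are skipped, never fabricated.

**Rhythm plausibility.** Threshold detectors produce *something* on pure
noise. The analysis command therefore gates on R-to-R regularity: sinus
rhythm, even with heavy jitter, keeps the robust RR coefficient of
variation (MAD/median) below ~0.05, while pseudo-rhythms detected in
beat-free noise exceed 0.3. Inputs past the gate (threshold 0.15) produce
an explicit "no beats" report instead of fabricated statistics. The gate
assumes roughly regular rhythm — arrhythmia analysis is out of scope.

## PTT pairing, cleaning, and fitting

Pairing searches, for each R-peak, the earliest inflection in
`(r + 0.1 s, r + 0.6 s]`. The physiologic window matters: an unbounded
"next inflection" rule silently mis-pairs whenever a pulse is dropped,
assigning the following beat's pulse to the wrong R-peak. Each inflection
is consumed at most once, so pairing is injective and order-preserving;
R-peaks without a candidate are dropped.

Outlier flagging compares each beat's PTT with a 31-beat running median
and flags deviations beyond 5 local MADs; values are flagged, never
altered. One caveat is documented rather than hidden: on a *very* sharp,
nearly noise-free transient, the running median lags the true course and
the first beats of the transient can be flagged. With realistic beat noise
(≥ 3 ms SD) this does not occur; for idealized data either fit the
unflagged series or widen `win_beats`.

The intervention fit runs Levenberg–Marquardt least squares with the
stimulus times fixed at the supplied hints and four free parameters
(baseline, delta, tau_on, tau_recovery; taus bounded below at 0.1 s). Five
deterministic starts span the physiological tau range (5–150 s); the
best-RSS convergent fit wins, making results reproducible without global
optimization. A delta start of exactly zero would zero the tau gradient
columns, so it is nudged to a small negative value. Parameter recovery,
measured over 20 seeded replicates with recovery constants across
20–120 s, 0.9 beats/s and 5 ms beat noise, keeps the median relative error
of `tau_recovery` around 3%, well inside the 10% validation bound.

Units: PTT is seconds internally everywhere; the interface (CSV export,
phase summaries, printed fits) reports milliseconds. The conversion happens
only at reporting boundaries.

## Session profiles

The `TS240-90` therapy profile encodes: compression on air to 2.4
atmospheres absolute, three 30 min pure-oxygen periods separated by two
10 min air breaks at pressure, and decompression to 1 ATA with continued
oxygen. Ramp durations are not standardized in the scheme description, so
they default to 15 min each and are configurable. The oxygen duty cycle —
90 min of isopressure oxygen out of a 1440 min day — is 6.25%, the
motivating observation that the presumed effective agent of daily
hyperbaric therapy is present only a small fraction of the time. The
nicotine functional-test timeline (5 min rest, 5 min smoking, 10 min rest)
is available as both a phase table and a simulation preset with the
stimulus placed at 300–600 s.

## Problem sizes and numerical conventions

The test suite validates on: 60–120 s recordings at 1 kHz for end-to-end
pipelines; 300–900 s beat series for HRV and fit-recovery statistics; 20
seeded replicates for the tau-recovery property. These sizes give stable
statistics (≥ 300 beats where sampling distributions are asserted) while
keeping the default suite fast. Sample index 0 corresponds to t = 0; all
fiducial times are in seconds from recording start; degenerate inputs
(flat signals, empty timelines, constant series) return well-defined empty
or null results rather than errors wherever the operation has a natural
zero case, and named error conditions (`pttkit_param_error`,
`pttkit_io_error`, `pttkit_analysis_error`, plus file-format subclasses)
otherwise.

## Known limitations

* White RR jitter and fixed per-beat morphology: passing tests demonstrate
  correct *mechanics*, not robustness to real-world HRV structure,
  morphology drift, or arrhythmia.
* Red/IR channels carry no desaturation information; SpO₂ is out of scope.
* Artifact detection is amplitude-only; slow-ramp artifacts below the
  robust-z threshold pass through (they are largely removed by the
  high-pass instead).
* The intervention model is single-exponential in both directions; multi-
  phasic pharmacokinetics would need a richer model than the fitter offers.
* The rhythm-plausibility gate trades arrhythmia tolerance for noise
  robustness; it is a reporting gate in the analysis command, not a
  property of the detector itself.
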