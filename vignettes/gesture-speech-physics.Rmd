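---
title: "Methods: beat-locked analysis of gesture-speech coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beat-locked analysis of gesture-speech coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

When a speaker rhythmically moves an arm or wrist while talking, the physical
impulse of each movement — particularly the abrupt braking ("beat") at the
bottom of a downward stroke — is transmitted through the trunk and
respiratory system and can perturb voice acoustics. The paradigm this
package implements compares three within-subject conditions (no movement,
wrist movement, arm movement at a target tempo of 80 BPM ≈ 1.33 Hz) and asks
three questions:

1. Does moving (and moving a heavier effector) raise the trial-average
   fundamental frequency (F0) and amplitude envelope of speech?
2. Are acoustic modulations time-locked to a specific phase of the movement
   cycle — namely the deceleration phase just before maximum extension?
3. Does the magnitude of the braking impulse (maximum deceleration, scaled
   by effector mass) predict the height of co-occurring acoustic peaks?

`gesturespeech` implements the full analysis pipeline for these questions,
plus a synthetic-session generator that injects *known* coupling so that
every pipeline stage can be validated against ground truth. All empirical
statements below are the ones the package's test suite and acceptance
script themselves compute.

## Signal definitions

**Amplitude envelope.** The modulus of the analytic signal
$|x(t) + i\,\mathcal{H}[x](t)|$, smoothed with a Hann kernel whose length is
`fs / 5` samples (a "5-Hz window", i.e. 200 ms), then resampled to the
240-Hz grid shared with the motion capture. Because the Hann smoothing
band-limits the modulus two orders of magnitude below the 120-Hz output
Nyquist, the resampling is done by linear interpolation onto the target
grid rather than polyphase decimation (44100/240 = 735/4 is an awkward
rational ratio and the anti-alias work is already done by the kernel).
The envelope is a *defined-as-smoothed* quantity: recovery of a generator's
ground-truth contour is therefore judged against the same smoothing applied
to the truth (`smooth_truth_envelope()`); the raw truth contour contains
syllable gates and frame-rate jitter that no 200-ms smoother can or should
follow.

**F0 track.** A frame-wise autocorrelation tracker on the same 240-Hz grid,
with sex-appropriate search ranges (male 50–400 Hz, female 80–640 Hz). The
audio is decimated to ≈ 8 kHz, frames of 2.5 periods of the range floor are
autocorrelated by FFT, and the candidate lag maximizes the *biased*
normalized autocorrelation minus a small per-octave cost — the natural decay
of the biased estimator with lag is what keeps octave-down errors rare —
while voicing strength is assessed on the bias-corrected value
(threshold 0.45, a conventional periodicity-strength default; the original
instrumentation does not publish one). Peak lags are refined by parabolic
interpolation, and a post-pass enforces ≤ 40% frame-to-frame change within a
voiced run, correcting by octave or unvoicing the frame. The tracker
identity is deliberately encapsulated: downstream analyses consume only
voiced runs and F0 values.

**Vocalization events.** Maximal uninterrupted runs of voiced frames
(`min_gap_ms = 0` keeps the strict definition; merging is available as
configuration). Duration in ms, the envelope-peak time within the event, and
the interval between consecutive events' envelope peaks give the two
speech-rate measures, both reported in Hz as `1000 / mean(ms)`.

**Kinematics.** The vertical position is low-passed with a first-order
Butterworth at 30 Hz applied forward–backward (zero phase, so event times
are not lag-shifted; edges are handled by odd-reflection padding so
constants and ramps pass through unchanged). Velocity and acceleration are
central differences, each re-filtered with the same filter. Maximum
extension is the local minimum of filtered position whose excursion —
measured against the highest position within one minimum period on either
side, which is robust to sensor-noise micro-maxima — exceeds
`min_amplitude_cm` (default 2 cm), with events at least `min_period_s`
(default 0.4 s) apart. The deceleration onset is the velocity minimum (peak
downward speed) in the preceding half second; maximum deceleration is the
absolutized extreme of the braking (upward) acceleration within the 200 ms
before extension. Movement tempo is monitored by a Morlet continuous
wavelet transform (ω₀ = 6, 96 log-spaced frequencies over 0.5–3 Hz); the
ridge is the per-sample power argmax, with compliance measured against the
paradigm's ±10% feedback region (72–88 BPM around 80 BPM).

## Epoching, the surrogate baseline, and the three models

Epochs slice the (participant-z-scaled) envelope and the F0 track onto a
fixed 193-sample grid spanning −400…+400 ms around each maximum extension
(800 ms ≈ one 1.33-Hz cycle of 752 ms plus margin), by nearest-grid
alignment with no interpolation. Beats within 400 ms of a trial edge are
skipped and counted. Consecutive epochs may overlap in time; that is a
property of the window choice, not an error.

The **surrogate baseline** re-pairs each passive-condition trial's speech
with the beat times of a randomly chosen movement trial *of the same
participant*, without permuting either series. It preserves all marginal
structure of speech and movement and destroys only their alignment, so any
beat-locked structure surviving it is chance-level. Because passive trials
have no beats of their own, the passive condition enters trajectory space
only through this pairing, and the surrogate is therefore the reference
level of the trajectory models.

1. **Condition contrasts** (per-trial summaries):
   `response ~ condition + (1 | participant)`, passive reference, plus a sex
   term for F0. Responses: participant-z-scaled envelope and F0 in Hz.
2. **Trajectory smooths** (epochs): one independently-penalized thin-plate
   smooth of epoch time per condition, parametric condition terms,
   participant random intercept, and a participant random slope over time
   where the fit supports it (dropped with a flag otherwise). Basis
   dimension `k = 20` over 193 grid points (exposed as configuration).
   Per-condition smooth p-values test nonlinearity of each trajectory;
   difference curves against the surrogate reference are computed from the
   fitted model via the linear-predictor matrix with pointwise standard
   errors (random-effect columns cancel exactly in the difference) and a
   Wald p-value at the difference peak. Separate per-condition smooths are
   used rather than a shared smooth plus difference smooths because, under
   penalization, the shared-smooth construction lets the reference
   trajectory absorb structure common to the movement conditions, which
   distorts both the reference curve and weak difference curves.
3. **Deceleration scaling** (trial means of deceleration-window features):
   for each beat, the closed window [−200, 0] ms before extension is
   intersected with overlapping vocalizations; acoustic maxima over the
   overlap and the window's maximum deceleration give one observation per
   (beat, vocalization) pair, averaged within trial. Envelope model:
   `max_env ~ max_decel` with participant random intercept and slope; F0
   model adds condition (wrist reference) and its interaction with
   deceleration. The deceleration predictor is standardized inside the fit
   (its SD in cm/s² is reported); on convergence failure the random slope is
   dropped and flagged.

No multiple-testing correction is applied across the two acoustic
responses, matching the paradigm's reporting conventions.

## What the generator emulates — and what it does not

`generate_session()` builds sessions with known coupling:

* **Movement**: quasi-periodic vertical strokes whose per-cycle frequency
  follows a mean-reverting random walk around 1.33 Hz (SD 0.04 Hz/cycle);
  the downstroke phase is power-law warped (`beat_sharpness`, default 2) so
  the stroke ends in an abrupt stop at the position minimum — sharpness 1
  recovers a pure sinusoid, which is the closed-form oracle used in tests.
  Stroke amplitude is 10 cm (wrist) vs 25 cm (arm) with lognormal
  trial-level (CV 0.2) and cycle-level (CV 0.1) multipliers: movers do not
  reproduce amplitude exactly, and this within-condition spread of peak
  deceleration is precisely what makes deceleration slopes and the
  condition × deceleration interaction identifiable, as in real data.
  Sensor noise (SD 0.05 cm) is added last; ground truth is computed on the
  noiseless trace.
* **Speech**: alternating voiced/pause runs with lognormal durations
  (means 160 ms and 200 ms — yielding trial-average vocalization rates in
  the ~5–8 Hz range typical of running speech); baseline F0 is sex-dependent
  (female 187 Hz, male 73 Hz lower) with participant random intercepts
  (SD 15 Hz), slow drift, and jitter; the envelope analogously, gated to
  near zero in pauses.
* **Coupling**: at each beat, a Gaussian bump (FWHM 120 ms) centered 100 ms
  before maximum extension — the middle of the deceleration window — is
  added to the envelope and F0 inside voiced intervals, with height
  `mass_factor(condition) × β × max_decel`. Mass factors are 0/1/2
  (passive/wrist/arm; the 2:1 arm:wrist ratio is a free choice, the
  paradigm quantifies no effector masses). Defaults: β_env = 3 × 10⁻⁵ per
  cm/s², and F0 coupling *only in the arm condition*
  (β_F0 = 10⁻³ Hz per cm/s², i.e. transient bumps of roughly 5–11 Hz),
  reflecting that F0 is uniformly less affected than the envelope and that
  F0–deceleration scaling is a high-effector-mass phenomenon. Sustained
  condition-level offsets (envelope +0.10/+0.20 units, F0 +1.6/+3.5 Hz for
  wrist/arm) model the overall acoustic elevation under movement and are
  the recovery targets for the condition-contrast models.
* **Audio**: a 6-harmonic complex with 1/k roll-off following the true F0,
  scaled by the true envelope, with a fixed global gain (per-trial
  normalization would distort between-condition level differences) and a
  low noise floor in pauses. Bumps falling wholly in pauses are recorded in
  the truth but leave no acoustic trace, mirroring an analysis that only
  sees vocalized windows.

The generator emulates the *statistical structure* the analysis assumes; it
does not simulate articulation, respiration, or intelligible speech. Passing
tests therefore demonstrate that the pipeline recovers injected coupling of
realistic size and timing from realistic signal-to-noise, not that any
particular real dataset exhibits such coupling.

## Numerical choices and degenerate inputs

* Hilbert transform and smoothing run via FFT with zero padding to
  composite lengths; edge samples are treated as edge region by every
  consumer.
* Nearest-grid epoch alignment never interpolates by more than one sample;
  the epoch grid is computed once and shared bitwise by all epochs.
* Windows are closed at both ends on the sample grid; a vocalization's
  offset frame itself is unvoiced (half-open event intervals).
* Degenerate inputs fail loudly: zero participant-level envelope variance
  (z-scaling impossible), single-condition data, passive trials carrying
  beats, out-of-range synthesis F0, non-uniform motion timestamps.
* Trials with no vocalization events report missing (not zero) rates.
* Deceleration-model predictors are standardized inside the fit to keep the
  random-slope covariance well-scaled; slopes are reported per SD with the
  SD attached.

## Problem sizes used by the test and acceptance suites

The validation suites choose sizes that keep the full run in the tens of
minutes on one CPU while preserving the study's statistical geometry:
study-scale parameter recovery uses 37 participants × 3 trials per condition
(333 trials, near the paradigm's 419), trial durations drawn around 26 s
(SD ≈ 7 s), and audio rendered at 16 kHz (ample for envelope content and
F0 ranges up to 640 Hz); null calibration runs 200 simulated zero-coupling
sessions of 10 participants × 2 trials per condition — per-participant
z-scaling needs several trials per participant before its scale estimates
decouple from the trial means being contrasted, so calibration designs
keep at least six trials per speaker; beat-detection fidelity
pools 50 seeded movement trials, with matching evaluated on the trace
interior (edge beats are unobservable in principle and are excluded
downstream by the 400-ms edge rule).

## Known limitations

* The F0 tracker is a deliberately compact autocorrelation design; it is
  validated end-to-end against the generator's harmonic synthesis, not
  against hand-labeled natural speech.
* The surrogate baseline assumes each participant has at least one passive
  and one movement trial; participants lacking either are excluded with a
  log entry.
* The deceleration-onset estimate (velocity minimum before extension) is
  computed per event; a grand-average version is available for plotting but
  no inferential use is made of it.
* x/y motion channels are ignored by design; the paradigm's instructed
  movement is vertical.
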