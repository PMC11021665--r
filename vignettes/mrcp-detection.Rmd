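---
title: "Detecting movement-related cortical potentials in real time: models, choices, and limits"
author: "mrcpbci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting movement-related cortical potentials in real time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Brain-computer-interface neurofeedback for motor rehabilitation pairs a
user's *motor attempt* with immediate sensory feedback (here,
neuromuscular electrical stimulation), on the Hebbian premise that
feedback arriving while the sensorimotor cortex is most active
strengthens the sensorimotor loop. The EEG signature this package
detects is the movement-related cortical potential (MRCP): a slow
(0.05-10 Hz) negative deflection that begins roughly 1.5-2 s before
movement onset and reaches its most negative point - the peak negativity
(PN) - within about half a second of it. The engineering task is to fire
a trigger inside the one-second window around the cued movement
([2500, 3500] ms after preparation onset), as close to the trial's PN as
possible, from streaming EEG, every 50 ms.

`mrcpbci` implements the full loop - synthetic EEG generation,
preprocessing, calibration, four detectors, a deterministic re-creation
of the real-time trigger loop, session-to-session transfer learning, and
the evaluation metrics - so that every stage is testable end to end
without any recorded human data.

## The trial protocol

A session is a sequence of 5-trial blocks; each 10-s trial is: 3 s relax
cue, then a 3-s preparation bar (trigger code 6 marks its start and
defines time zero for the real-time loop; code 8 marks the trial start,
code 7 closes a block), with the cue to dorsiflex when the bar fills at
3000 ms, then movement and a 3-s hold. One hundred trials (20 blocks) is
the standard session scale.

## The synthetic EEG generator

The generator (`simulateSession()`) is the package's study-condition
definition, not a throwaway fixture. Each trial embeds an MRCP template
into multi-channel background noise on a 64-channel extended 10-20
montage at 500 Hz.

**Template.** Two components, mirroring the classical decomposition of
the MRCP: a slow readiness drift (convex cubic ramp, zero until 1750 ms
before the cue, accelerating toward the PN - shallow early, steep late)
carrying 65% of the depth, plus a sharper "motor potential" peak
(Gaussian, SD 100 ms) centered on the trial's PN carrying the remaining
35%. The full depth (-10 uV at the focal channel by default) is attained
exactly at the PN sample. After the PN the slow component rebounds to
baseline over 1 s. The PN latency is the cue time plus truncated-normal
jitter (SD 150 ms, truncated at +-450 ms), so every ground-truth PN lies
inside the detection window and the trial bookkeeping (true positive /
false negative) is always well defined. The sharp component matters: with
a ramp alone the template is nearly flat near its minimum, and the
per-trial argmin that defines the "true" PN would wander by hundreds of
milliseconds under even mild noise.

**Topography.** Gaussian gain falloff (SD 0.25 head-circle units) around
Cz - the lower-limb representation sits near the vertex. Distant
channels (e.g. O2) receive well under 10% of the focal energy.

**Background.** Per channel: 1/f ("pink") noise of 4 uV RMS, a 10 Hz
alpha oscillation (0.5 uV, random phase), and 0.5 uV white sensor noise.
A fraction 0.97 of the pink-noise *variance* is spatially uniform across
the scalp, emulating volume-conducted far-field activity; a surface
Laplacian cancels it exactly, while the remaining ~0.7 uV RMS is
channel-local and survives. Real EEG background is spatially
*correlated*, not identical, and its local residue is not white-in-space;
the simulator's dichotomy is the simplest structure that gives the
Laplacian a realistic job. These amplitudes are design values - the
source publication reports no amplitude or SNR statistics for its
recordings - chosen so that the default pipeline operates where the
method is intended to work: per-trial PN recovery errs by a few tens of
milliseconds and the default LSTM exceeds 90% held-out sample accuracy.
Passing tests therefore demonstrate correctness of the machinery under
these conditions, not performance on any real recording.

**Drift.** `applySessionDrift()` perturbs template amplitude, PN latency
center, and per-channel gains, to emulate session-to-session variability
for the transfer-learning tests. Latency jitter is additionally clamped
so the PN never exits the detection window.

Everything is a pure function of (plan, seed).

## Preprocessing

The chain is band-pass 0.05-10 Hz, surface Laplacian over the full
montage, then restriction to the 20 sensorimotor channels (FC5...CP6)
that feed every detector.

* **Filter realization.** Second-order Butterworth high-pass and
  low-pass sections. The offline path is zero-phase
  (forward-backward, `signal::filtfilt`), used for everything that needs
  unbiased timing: PN extraction, the calibration ERP. The real-time
  path must be causal; it applies each section twice forward, so its
  *magnitude* response equals the offline chain's and the two paths
  differ only by the causal phase delay. The causal high-pass has a
  multi-second startup transient (time constant ~1/0.05 Hz); since a
  live amplifier streams long before detection starts, the filter state
  is warmed up by constant padding before each block.
* **Laplacian.** Channel minus the mean of its nearest montage
  neighbors (orthogonal grid neighbors, the "small" Laplacian); the
  neighbor map is part of the `Montage` object and configurable.
* **Virtual Cz.** The mean of C1, C3, Cz; the series on which per-trial
  PN is defined.

## Calibration

Epochs run from 3 s before to 1 s after the cue. The per-trial PN is the
minimum of the virtual-Cz epoch within the closed window [cue - 500,
cue + 500] ms (ties break to the earliest sample); their mean is the
open-loop trigger time of the average-PN detector. The calibration ERP
is the pointwise trial average per channel.

**Threshold polarity.** The PN is a negative deflection, but the
threshold rule is stated as "k standard deviations *above* the mean" of
the rest period, with a trigger when the signal "exceeds" it. The
detector therefore operates on the negated Cz series, making the PN a
positive peak; mean and SD are computed on the negated rest segment
(the first second of the relax phase inside the epoch). The choice of
k in {1, 2, 3} is a configuration default (k = 2) with an optional
automatic rule - the smallest k whose threshold is never crossed in the
calibration rest windows - replacing the operator's visual choice, which
must not block batch evaluation. The threshold is computed on the causal
ERP so that it lives on the same scale as the live packets.

**Labeling.** Two schemes create supervised data: *time-based* labels
take the cue as reference, *PN-based* labels each trial's own PN. One
second around the reference is motor intent, the preceding second rest,
everything else unlabeled and excluded from training. Windows are
half-open, so each trial contributes exactly 500 + 500 labeled samples
at 500 Hz.

## Detectors

All four share one contract: given the preprocessed 20-channel
representation, produce a trigger decision at each 50 ms tick.

* **Threshold**: fires when the packet mean of the (negated) Cz series
  strictly exceeds the calibration threshold.
* **Average-PN**: open loop; fires at the first tick at or after the
  mean calibration PN time. No EEG is consulted.
* **MLP**: labels each sample from its instantaneous 20-channel vector;
  three hidden layers of width 20, ReLU, SGD (learning rate 0.01, batch
  8). The two-layer variant is available.
* **Bidirectional LSTM**: labels each sample using temporal context; 100
  units per direction, dense layer, per-step softmax; Adam, 100 epochs.
  Batch size (8) and the cross-entropy loss are not specified upstream
  and mirror the MLP's settings.

Both networks are implemented in compiled code (RcppArmadillo) with full
backpropagation(-through-time), verified against numerical gradients;
training is bit-deterministic given the seed, and serialized models
reload with identical behavior.

**Sequence length and the position shortcut.** With time-based labels
every training epoch has its labeled windows at the same absolute
positions. A bidirectional LSTM trained on whole 1500-sample epochs can
reach near-perfect training accuracy by counting samples from the
sequence edges - a solution that transfers not at all to the 25-sample
packets classified at run time, where no absolute position exists. The
LSTM is therefore trained and evaluated on packet-length tiles
(`seq_len = 25` samples) of the labeled span: exactly the shape the
real-time loop feeds it. This removes the shortcut (the label-shuffle
control then sits at chance) and makes held-out sample accuracy an
honest estimate of deployment behavior.

**Train/deploy filter paths.** The labeled dataset is built on the
zero-phase path by default (`calibrateSession(trainOn = "offline")`):
that path has no group delay against the cue-locked labels and is where
the detectors separate the classes best. The real-time harness, however,
can only filter causally, and a classifier trained on zero-phase data
faces a genuine covariate shift there - the causal stream differs by
phase delay and slow causal tails even with matched magnitude response -
which inflates rest-window false triggers relative to the offline world.
`trainOn = "causal"` builds the dataset on the deployment
representation instead, trading per-sample accuracy (the cue-locked
labels are misaligned by the causal delay) for train/deploy consistency.
The gap between these two worlds is real and is reported, not hidden;
see the limitations below.

**Input dimension.** The LSTM input is configurable among 20 (the
sensorimotor channels - the default, since the preprocessing chain
declares them the detector inputs), 21 (adding virtual Cz as an extra
input), and 64 (the full montage); the upstream description is
internally inconsistent on this point and the package does not guess.

## The real-time harness

`runTrial()` re-creates the live loop deterministically: time zero at
trigger 6; a decision every 50 ms from 1500 ms; at each tick the latest
25 samples (50 under the 100-ms-packet variant) are classified and the
trigger fires when at least `ceil(0.8 x 25) = 20` samples are labeled
motor intent (or the threshold / average-PN rule for those detectors).
A trigger with a decision timestamp in [1500, 2500) ms is a false
positive (rest window), in [2500, 3500] ms a true positive. If nothing
fired by 3500 ms, an automatic fallback trigger is issued; a classifier
trigger at exactly 3500 ms counts as a true positive, not fallback. The
fallback is a configuration flag (on by default, matching the
implemented system; off matches the stated plan for future cohorts).

All windows are expressed in milliseconds, not packet indices, so the
bookkeeping is invariant to the packet-length choice. Trials end at the
first trigger; per-tick decisions are nevertheless logged across the
whole detection span, so the offline false-negative rule - no PN-window
packet satisfies the trigger rule (default), or no PN-window packet is
entirely motor intent (the strict, literal reading) - is computed
independently of the live event, and an independent recount of the logs
must reproduce the live categories exactly (this is asserted in the
tests).

## Transfer learning

To reduce calibration in later sessions, the trained LSTM's input stage
and bidirectional layer are frozen, a fresh 100-unit bidirectional layer
plus a new softmax head are stacked on top, and only the new parts are
trained on the first 25 labeled trials of the new session. "First two
layers" is read as {sequence input, original bidirectional layer}; the
head is retrained. Fine-tuning epochs default to the base training's
100; early stopping is off for determinism. Inputs are z-normalized
per channel with statistics fitted on the *new* session's calibration
trials - per-session fitting is the only reading under which input
normalization counters session-to-session drift - and the state is
stored in the model, never refit silently. Frozen parameters are
byte-identical before and after fine-tuning, which the tests assert.
The upstream abstract mentions reducing calibration to 20 trials while
the methods say 25; the default is 25 and the count is a parameter.

## Evaluation

* **Sample accuracy**: correctly labeled samples over labeled samples.
  Reported alongside, never merged with, the *trial-level* rates of the
  session report (accuracy = % of trials triggered in the PN window,
  plus FP / FN / fallback percentages), because the upstream accuracy
  wording mixes the two readings.
* **Detection error**: trigger time minus trial PN per
  classifier-triggered trial (negative = early), summarized as mean,
  sample SD (n-1 throughout the package), and RMSE; fallback trials are
  excluded and counted separately. RMSE² = mean² + var·(n-1)/n holds to
  numerical tolerance.
* **Fivefold evaluation**: the stated protocol fixes the chronological
  50/50 split *and* calls for five folds; the only consistent reading -
  five seeded repetitions of the fixed split - is implemented.
* **Two-sample comparison**: the classic pooled-variance two-sample
  t test, two-sided.
* **ERD**: band power (mean periodogram over epochs, mean-detrended, no
  taper) in alpha (8-12 Hz) or beta (13-30 Hz);
  ERD = 10·log10(P_rest / P_move) dB, positive = desynchronization,
  averaged over the channel set; plus the laterality index
  (contra - ipsi) / (contra + ipsi). The full ERSP machinery
  (bootstrap-masked spectrograms, ICA decomposition) is out of scope.

## Numerical conventions

Sample indexing is 0-based at the API boundary (trigger events, trial
slices); time windows are half-open `[start, end)` in ms except the
closed PN detection window; ms-to-samples conversion is
`floor(ms * rate / 1000)`. Ties in argmin break to the earliest sample.
Random draws derive from a single plan seed; per-stage seeds derive from
the global seed through a fixed integer stream so stages can be rerun
independently. The internal bundle format is R serialization of the S4
containers: one file, bitwise round-trip, no external dependencies.

## Problem sizes in the test suite

The unit tests run the machinery at small scale (tiny networks, sessions
of 1-4 blocks). The acceptance suite runs the headline checks at the
scale the package treats as a session: parameter recovery on 100 trials,
the default 100-unit/100-epoch LSTM on the default 100-trial session
with a chronological 50/50 split, reduced-size configurations (fewer
hidden units and epochs, smaller sessions) for the controls that need
many repetitions - the label-shuffle control, the SNR ladder, and the
transfer comparisons. Those reduced sizes are choices about where the
property is informative per unit of compute, stated here so the suite's
scope is explicit.

## Known limitations

* The simulator's noise is stationary and spatially dichotomous
  (uniform + independent); no eye blinks, EMG bursts, electrode pops, or
  realistic volume conduction. Detector rankings under these conditions
  need not match rankings on real EEG.
* The causal/zero-phase pairing leaves a genuine distribution gap
  (phase delay, slow causal tails). Under the default synthetic
  conditions a zero-phase-trained LSTM is highly separable on held-out
  zero-phase data yet false triggers far more often on the causal tick
  stream; causal-path training narrows the deployment gap at a
  per-sample accuracy cost. Session-level trigger rates on the causal
  harness should therefore be read on their own terms, not as estimates
  of the offline sample accuracy.
* With time-based labeling, motor intent begins 500 ms before the cue
  by definition, so a confident classifier legitimately triggers near
  the start of the PN window; detection errors against the per-trial PN
  are then strongly negative (early firing) by construction, unlike a
  detector whose confidence only builds near the actual negativity
  peak.
* The threshold detector inherits the fragility for which it was
  discarded upstream: a threshold set from the trial-averaged ERP's rest
  statistics is far below single-trial noise excursions, so it false
  triggers on most trials under the default conditions. It is retained
  as a faithful baseline, not a recommendation.
* Transfer learning supports one frozen base; chaining a transferred
  model as the base of a further transfer is deliberately rejected
  rather than silently deepening the stack.
* Under the simulator's drift model, transfer shows no measurable
  accuracy benefit over fresh training on the same 25 trials (the test
  suite finds a tie to slightly negative gap): the drift is a global
  amplitude/latency transformation that the per-session z-normalization
  already removes, after which 25 default-SNR trials saturate the task.
  The cross-session benefit claimed for real EEG rests on richer
  variability than this mechanism generates, and the corresponding
  directional check is allowed to fail rather than enriching the drift
  model to manufacture it.
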