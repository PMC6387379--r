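---
title: "Acoustic detection methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic detection methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecodetect)
```

`ecodetect` re-creates, on the desktop, the class of detection algorithms
that run on low-power autonomous acoustic sensors: the device listens into
a fixed-size sample partition, computes a cheap frequency-domain statistic,
and decides whether to keep a recording. This vignette explains the models
behind each detector, the parameters that matter, what the synthetic
fixtures do and do not emulate, and the design decisions taken where the
underlying algorithm descriptions left room.

## Narrowband energy: the Goertzel filter

Every detector consumes band magnitudes produced by `goertzel_magnitudes()`.
A window of `L` samples is Hamming-weighted and driven through the
second-order recurrence `y_j = h_j s_j + c y_{j-1} - y_{j-2}` with
`c = 2 cos(2 pi f / f_s)`; the reported value
`m = y_L^2 + y_{L-1}^2 - c y_L y_{L-1}` equals the squared modulus of the
windowed DFT at `f`, at O(L) cost instead of O(L log L). Three conventions
are worth stating because they differ from textbook treatments and all
downstream thresholds depend on them:

* **No square root.** `m` is the *squared* magnitude; thresholds are
  calibrated on that scale.
* **Hamming indexing.** `h_j = 0.54 - 0.46 cos(2 pi j / L)` with
  `j = 1, ..., L` — denominator `L`, not the `L - 1` of the textbook
  window. The first coefficient is therefore not the symmetric textbook
  value; the difference is immaterial for detection but matters for
  bit-level reproduction, so it is frozen in the tests against a direct
  DFT oracle.
* **Normalized samples.** 16-bit PCM is divided by 32768 into `[-1, 1)`,
  making thresholds device-independent.

The filter length comes from the bandwidth rule `L = round(4 f_s / B)`
(`filter_length()`). Detector configurations may override `L`: the bat
detector uses `L = 256` (the rule gives 250 for a 4 kHz band at 250 kHz)
so that its 128,000-sample partition divides into exactly 500 windows.
Buffers not divisible by `L` drop the trailing partial window — a partial
window cannot produce a valid magnitude.

## Bat detector: sliding median over 500 windows

A 5 ms echolocation call occupies ~1250 samples at 250 kHz, i.e. about 5
of the 500 Goertzel windows in one 512 ms partition. A single-window
threshold would be at the mercy of one noisy window, so the detector takes
the median of `sliding_width = 5` consecutive magnitudes, stepping by
`floor(width/2)` so every window is covered at least twice, and triggers
on the first median at or above the threshold (ties trigger; one event per
partition, mirroring record-on-trigger firmware).

The width must be tuned to the call: if the sliding window spans more than
twice the call length, over half of its values are background and the
median collapses to the noise floor. `bat_config()` warns when
`sliding_width * window_len` exceeds twice a 5 ms call, and the test suite
checks both directions (width 5 separates call from background strictly
better than width 15; width 15 misses a call that width 5 catches at a
matched threshold).

The duty-cycle emulation (`run_duty_cycled()`) replays the deployment
schedule offline: sleep 2 s, listen 512 ms, analyse, and on a trigger mark
a 10 s recording and resume after it.

## Cicada detector: an amplitude-invariant band ratio

The target song is a sustained buzz with a dominant 14 kHz component; the
main confusables are wind (broadband, strong at both 8 and 14 kHz) and
intermittent broadband cricket chirps. Each 8192-sample partition yields
64 pairs of 14 kHz and 8 kHz magnitudes; the statistic is the median of
`m14 / max(m8, epsilon)`. Two properties carry the detector:

* **Gain invariance.** Goertzel magnitudes are homogeneous of degree two
  in the input, so the ratio — and hence the trigger decision — is exactly
  invariant to amplitude scaling. Wind rejection is spectral, never based
  on loudness.
* **Median robustness.** A chirp occupying a minority of the 64 windows
  cannot move the median, while a sustained buzz lifts nearly every
  window.

Edge conventions: the median of 64 values is the mean of the 32nd and 33rd
order statistics; a window with zero signal-band magnitude contributes a
ratio of exactly 0 (so digital silence cannot trigger);
`epsilon = 1e-12` on the normalized magnitude scale.

## Gunshot detector: five-state HMM over three-band features

A gunshot is an impulse whose high-frequency content decays faster than
its low-frequency content as it propagates. The detector works in the
time domain: 256 windows of (400, 1200, 2000 Hz) magnitudes per 4.096 s
span are decoded into silence (S), noise (N), initial impulse (I),
decaying impulse (D) and tail (T) states, and a gunshot is declared when
the decoded path contains an I, later a D, and later still a T. Design
choices where the model family left room:

* **Emissions** are independent log-normals per state and band,
  log-densities summed — the simplest model consistent with three-band
  observations, with heavy right tails for close-range shots.
* **The 100x cap** on per-window state likelihoods is applied as a clamp
  in log space (values below `max - log(100)` are raised to that floor),
  per observation. This preserves the per-window argmax while enforcing
  the stated bound; whether the original firmware applied the cap per
  observation or globally is not documented, so the per-observation
  variant was chosen and is exposed via `cap_factor`.
* **Topology**: S→{S,N,I}, N→{N,S,I}, I→{I,D}, D→{D,T}, T→{T,S,N}, all
  other transitions zero — the gunshot stages are strictly ordered, and
  an excursion that enters I must run through D and T. The topology is an
  assumption (the published state diagram is not machine-readable) and is
  fully configurable through the transition matrix of `gunshot_hmm()`.
* **Initial distribution**: uniform over {S, N}; an analysis span almost
  never begins mid-gunshot.
* **Overlapping spans**: the stream is partitioned into 2.048 s blocks
  and spans (1,2), (2,3), ... are each decoded, so every block is analysed
  twice and a shot straddling a boundary appears whole in one span.
  Duplicate detections within `merge_window_s = 2.048` s (one span of new
  audio) are merged keeping the earliest.
* **Numerical floors**: magnitudes are floored at `1e-30` before logs;
  Viterbi runs entirely in log space; ties in the argmax resolve to the
  first state in S, N, I, D, T order, making decodes deterministic.

## Supervised training

`fit_emissions()` moment-matches each state/band log-normal on the log
scale and requires at least two windows per state; an all-identical
magnitude set is rejected as degenerate, and small spreads are floored at
`sigma = 1e-3` to avoid near-degenerate spikes. `fit_transitions()` uses
only mean dwell times: under the memoryless dwell a mean of `d` windows
gives self-transition `1 - 1/d` (the unique choice consistent with a
first-order Markov chain), and the exit mass is split over the allowed
successors proportionally to observed successor counts, uniformly when a
state's exit was never observed. `simulate_states()` draws paths from the
fitted chain; because of the topology, every simulated excursion through I
runs through D and T, the same structural signature used for detection.

The packaged `default_gunshot_model()` is fitted by exactly this pipeline
on a fixed, seeded set of synthetic fixtures (12 gunshots at 20 dB plus
noise and near-silent spans), so the shipped model is reproducible from
code rather than stored numbers.

## Evaluation and resource estimators

`roc_curve()` sweeps thresholds over the unique observed statistics (plus
infinite endpoints), giving the exact step curve rather than a gridded
approximation, with trapezoidal AUC; the tests pin it to the Mann-Whitney
concordance probability and to an established ROC implementation.
`select_threshold()` maximizes TPR subject to an FPR cap, breaking ties
toward lower FPR and then the higher, more conservative threshold.
Storage arithmetic uses binary mebibytes (2^20 bytes) — the convention
under which a 12 h night of 16-bit 8 kHz audio is 659 MiB. The false-
trigger estimator exposes the duty-cycle period as a parameter
(`false_triggers(fpr, hours, period)`), since the expected count is just
`hours * 3600 / period * fpr`.

## What the synthetic fixtures emulate — and what they do not

`generate_fixture()` produces seeded, bit-reproducible audio with
machine-readable truth:

* **Bat pulses** use an FM-CF shape: a fast down-sweep from 70 kHz into a
  constant-frequency dwell at the 60 kHz terminal frequency over 5 ms.
  This matches pipistrelle-type calls, whose energy concentrates at the
  terminal frequency — and it is what makes the width-5 sliding median
  meaningful. A purely linear 70→50 kHz sweep was evaluated and rejected
  as the default: it spends roughly one window inside the 4 kHz detection
  band, so the median statistic never rises above background and no
  threshold can separate the classes; the FM-CF default reflects the call
  structure the detector was designed around. Per-fixture jitter of the
  terminal frequency (±500 Hz) and phase keeps distinct seeds
  decorrelated. A constant-tone pulse remains available.
* **Cicada buzzes** are tapered tones with ±50 Hz frequency jitter;
  **wind** is AR(1)-shaped Gaussian noise (coefficient 0.5 at 48 kHz),
  which carries substantial energy at both 8 and 14 kHz and so exercises
  exactly the confusion the band ratio suppresses; **cricket chirps** are
  20 ms broadband bursts at 1 s intervals.
* **Gunshots** superimpose three sinusoidal components at the feature
  frequencies with exponential decay constants 0.35, 0.18 and 0.08 s
  (larger at lower frequency, so the 2000 Hz band falls below 10% of its
  peak before the 400 Hz band), plus a 32 ms broadband click, over a ~1 s
  envelope.
* **SNR** is set in-band: the clean signal is scaled so the ratio of its
  band RMS over the event span to the background's band RMS matches the
  requested dB figure; fixtures verify this to within 1 dB. Fixture
  defaults use 20 dB for pulse/gunshot material and 10 dB for the buzz.

These fixtures deliberately model only the spectral/temporal structure
each detector keys on. They do not model acoustic propagation, terrain or
distance effects, reverberation, species variation beyond small frequency
jitter, competing biophony, or sensor self-noise. Passing the packaged
performance checks therefore demonstrates that the algorithms implement
their designs correctly and separate their intended signal classes under
controlled conditions — not that any particular field accuracy will be
achieved; thresholds and HMM parameters must be recalibrated on real
recordings for a real deployment.

## Shipped defaults and problem sizes

The bat (0.8) and cicada (4.3) default thresholds sit at the geometric
midpoint of the gap between background and signal statistics measured on
the synthetic calibration set (background maxima ~0.16 and ~2.1; signal
minima ~3.8 at 20 dB and ~9.0 at 10 dB respectively). A threshold placed
exactly at the smallest positive calibration statistic — the value the
FPR-capped selector returns when the classes separate perfectly — sits on
the class boundary and misfires on held-out data, so the midpoint is used
for the shipped defaults while `select_threshold()` remains the
recalibration tool. Both defaults respect a 0.01 false-positive-rate cap
by a wide margin on the calibration set.

The test suite sizes its simulations for a desk run: 20-30 fixtures per
class for the detector performance checks, 50 training fixtures for the
held-out gunshot check, 5000 windows for HMM parameter recovery, and
exhaustive path enumeration up to 8 observations for the Viterbi oracle.

## Known limitations

* The WAV reader supports exactly the format the recorders write: mono,
  16-bit, uncompressed PCM. Everything else is rejected rather than
  converted; there is no resampling.
* Training is fully supervised from labelled intervals; there is no
  Baum-Welch refinement.
* The cicada and bat detectors report events and marked recording spans;
  they do not emit the recordings themselves.
* The gunshot detection rule is structural (ordered I, D, T in the
  decoded path) and so reports no graded confidence beyond the decoded
  path composition.
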