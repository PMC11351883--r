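---
title: "Beat-by-beat left-ventricular hemodynamics from heart sounds and pulse waves: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beat-by-beat left-ventricular hemodynamics from heart sounds and pulse waves: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Left-ventricular (LV) hemodynamic parameters — peak systolic pressure (SBP),
minimum diastolic pressure (DBP), and the maximum rates of pressure rise and
decline (MRR = LV +dP/dt~max~, MRD = LV −dP/dt~max~) — are sensitive indices
of contractility and relaxation, but measuring them requires an
intraventricular catheter. Two non-invasive surface signals carry correlated
information: the phonocardiogram (PCG), whose first heart sound scales with
the pressure rising rate, and the photoplethysmogram (PPG), whose amplitude
tracks pulse pressure and whose arrival delay shortens as pressure rises.
`hemobeat` implements a beat-by-beat regression from one cardiac cycle of
PCG + PPG to the four-parameter tuple, together with everything needed to
train and evaluate it: preprocessing, cycle segmentation, reference-label
extraction from catheter pressure, record-level evaluation protocols, and a
coupled signal simulator that stands in for animal data.

## Preprocessing

All channels share a 1 kHz clock. Zero-phase (forward–backward) Butterworth
band-passes remove out-of-band noise without introducing inter-channel
delay: ECG 0.5–40 Hz, PCG 30–200 Hz, PPG 0.5–20 Hz, and LV pressure 0–20 Hz.
The one-way design order is 4 (effective order 8 after the
forward–backward pass); the signal is extended by odd-reflection padding of
three filter lengths at each end before filtering and trimmed afterwards,
which suppresses start-up transients on short records. Records at other
sampling rates are polyphase-resampled to 1 kHz first, because the model
window is defined in samples.

The pressure channel is deliberately a pure *low-pass*: its calibrated DC
level and the slow (tens of seconds) drug-induced excursion carry the
SBP/DBP labels, and a sub-hertz high-pass would subtract exactly that
component. One consequence worth knowing: a 20 Hz low-pass slightly rounds
the fastest systolic upstrokes, so extracted MRR saturates by a few percent
at the top of its range. This is a property of the measurement chain, not of
the extraction code, and it applies equally to training and evaluation
labels.

## Segmentation and quality screening

R-waves anchor the analysis grid. The detector is the classical
Pan–Tompkins cascade — 5–15 Hz band-pass, five-point derivative, squaring,
150 ms moving-window integration, adaptive dual thresholds with search-back
— with a 200 ms refractory period during which a larger integrated peak
*relocates* the current detection rather than being discarded (two
fiducials that close together must belong to one QRS complex). Detections
are refined to the local ECG maximum within ±50 ms, and RR intervals below
250 ms are rejected. Cycles are half-open R-to-R intervals in 0-based
sample coordinates; the trailing partial beat is dropped.

Quality screening is template-correlation gating, the standard
signal-quality-index approach: each cycle is resampled to a common length
and correlated with a running template (an exponentially weighted mean of
accepted cycles, update weight 0.1), and the score is the *smaller* of the
PCG and PPG correlations, compared against a threshold of 0.8. Two details
matter on real-looking data. First, heart sounds are narrow-band bursts
whose carrier phase is not coherent from beat to beat, so the PCG is
compared through its 30 ms magnitude envelope. Second, both the
pulse-transit delay and the heart-sound timing move with blood pressure, so
the correlation is maximized over lags (±30% of the template length) rather
than evaluated at zero lag. Flat-line segments (variance below 10^−12^) and
clipped segments (≥5 consecutive samples pinned at a channel rail) fail
regardless of correlation.

Model inputs are 1000-sample × 2-channel windows (PCG, PPG), zero-padded at
the tail. Cycles longer than 1 s cannot fit the window; they are excluded
with a warning rather than truncated (truncation would remove diastolic
content), with truncation available as a configuration choice.

## Reference labels

From each cycle's pressure segment: SBP is the cycle maximum, DBP the
minimum after the systolic peak (LV minimum pressure, which can be negative
relative to transducer calibration — this is not cuff diastolic pressure),
and MRR/MRD the extrema of the central-difference first derivative scaled
by the sampling rate. No extra smoothing is applied on top of the 20 Hz
channel filter.

Isolated spikes in the beat-to-beat label series (catheter artifacts that
survive screening) are repaired from nearby beats. The screen works on the
per-record first-difference series of each parameter. A classical
"mean ± 3 SD" rule on that series is self-masking: a single large spike
inflates the moment-based SD above the spike's own difference, so nothing
is ever flagged in short records. The package therefore uses the robust
equivalent — median and 1.4826·MAD of the difference series, flagged beyond
3 robust SDs — and identifies a *spike* as a beat whose two adjacent
differences are both extreme with opposite signs (an edge beat qualifies
through its single adjacent difference). Flagged beats are replaced by
linear interpolation of the nearest unflagged neighbours and marked
`repaired`. Constant-difference series (zero MAD) flag nothing, and the
repair is idempotent.

Training targets are SBP/50, DBP/10, MRR/2000, MRD/1000, which puts the
four parameters on comparable numeric scales so each contributes similarly
to the squared-error loss; the inverse scaling is exact.

## The network

The estimator maps a 1000 × 2 window to the scaled 4-vector:

* **Six residual 1-D convolution blocks.** Every convolution has kernel
  length 16; filter counts are 32, 32, 32, 32, 64, 64. Each block is
  pre-activated (batch norm + ReLU, omitted at the very start of block 1)
  and contains convolution → batch norm → ReLU → dropout (rate 0.2) →
  convolution; the second convolution's stride and the shortcut's
  max-pooling size are 2 in blocks 1, 3, 5 and 1 elsewhere, so the
  temporal length falls 1000 → 125. Where the channel count changes
  (block 5), the pooled shortcut passes through a 1×1 projection
  convolution — the standard way to keep an additive shortcut well-typed.
* **A bidirectional GRU** with 32 units per direction reads the 125 × 64
  feature sequence; the final hidden states of the forward and backward
  passes are concatenated into a 64-dimensional summary. (A GRU's final
  state is itself a learned aggregation of the sequence, which is why it
  is preferred here over temporal average pooling.)
* **Head:** batch norm → leaky ReLU (slope 0.01) → dense layer with 4
  cells.

Training minimises mean squared error on the scaled targets with Adam at
learning rate 0.001 (plain SGD selectable) and batch size 64; incomplete
trailing mini-batches are dropped so batch statistics stay well defined.
After every epoch the validation loss is evaluated with running batch-norm
statistics, and the returned model carries the weights of the epoch with
the smallest validation loss. One integer seed drives weight
initialisation, dropout masks and epoch shuffling, making training runs
bit-reproducible on a fixed BLAS.

The network is implemented from scratch in compiled single-precision code
(im2col + BLAS matrix products for the convolutions, hand-written
backpropagation through every layer, including the batch-statistics path
of batch norm and time-unrolled GRU gradients). The analytic gradients
were verified against central finite differences in a double-precision
build of the same source, layer type by layer type, to ~10^−8^ relative
error; the shipped test suite re-checks the float build through a
directional-derivative identity and a suite of descent/memorisation
properties.

## Evaluation protocols

All splits are at *record* level — a test record contributes no cycles to
training or validation, which matters because neighbouring beats are highly
similar and cycle-level splits would leak.

* **Within-subject five-fold (3-1-1):** a subject's records are shuffled
  into five near-equal subsets; each subset serves once as the test set
  while the remaining records are split 3:1 into training and validation.
* **Cross-subject:** all records of the other subjects train the model;
  the target subject's records are halved into validation and test, then
  the halves are swapped for a second pass.
* **Calibration:** identical to cross-subject except that one record moves
  from the target's validation half into training, giving the model a
  little individual information; the test set is untouched.

Per parameter the report contains ME, MAE, the SD of the mean-centred
errors (N−1 denominator), and Pearson's CC with a two-sided t-test p-value
(N−2 df) and a 95% Fisher-z confidence interval. Zero-variance series make
CC undefined; it is flagged rather than fabricated. Fold metrics aggregate
as an unweighted mean (a cycle-weighted mean is also reported).

## The synthetic study

The simulator emulates the drug-bolus experiment the estimator is designed
around: an anesthetized subject instrumented for ECG, PCG, femoral PPG and
LV catheter pressure, receiving an intravenous epinephrine bolus that
sweeps blood pressure and contractility over a wide range. It exists so
that every pipeline stage — and the estimator end to end — is testable
without animal data; its defaults are fixed study conditions, not tuning
knobs.

* **Trajectory.** Baseline (SBP 130 mmHg, DBP 2 mmHg, MRR 1900 mmHg/s,
  MRD −1950 mmHg/s, HR 110 bpm — pre-injection values typical of
  instrumented beagles) holds for 10 s; then each parameter follows a
  double-exponential rise/decay (τ~rise~ 6 s, τ~decay~ 20 s) whose peak
  scales with dose (0.5, 1, 2 units/kg map to 0.55, 0.75, 1.0 of the full
  effect: +120 mmHg SBP, −20 mmHg DBP, +6500 mmHg/s MRR, −3300 mmHg/s MRD,
  +40 bpm HR). Mild AR(1) wander plus 2% per-beat jitter adds realism.
  Across seeds and doses the per-beat parameters stay inside the pooled
  observed ranges (SBP [77, 272] mmHg, DBP [−47, 20] mmHg,
  MRR [106, 9181] mmHg/s, MRD [−5896, −70] mmHg/s).
* **Pressure beat.** A raised-cosine upstroke from end-diastolic pressure
  to SBP whose peak slope *equals* the requested MRR (the upstroke duration
  follows from T~up~ = π·ΔP/(2·MRR)), a raised-cosine decline to DBP whose
  steepest slope equals MRD, and a slow half-cosine diastolic refill.
  Because the kernel is analytic, the label extractor inverts it to within
  1 mmHg (SBP/DBP) and 2% (MRR/MRD) on noiseless beats — the closure that
  anchors the label tests. Parameter combinations whose slopes cannot span
  the pressures within the beat raise an explicit infeasibility error.
* **Couplings.** S1 is a Gaussian-modulated sinusoid at the upstroke with
  amplitude a₁·MRR + b₁ (the classical linear first-sound/contractility
  relation); S2 sits near end-systole with amplitude a₂·|MRD| + b₂. The
  PPG pulse is delayed by a transit time that falls with SBP and scaled by
  pulse pressure. Each coupling law carries a per-subject *compliance
  exponent* (1 = linear). This matters for the cross-subject protocol: an
  affine difference between two subjects' couplings is undone by the
  regression up to an affine remap — it inflates bias and spread but
  leaves Pearson correlation untouched — so the degradation that makes
  cross-subject transfer visibly worse in CC must come from curvature
  differences. The second built-in profile therefore differs in gains,
  offsets, carrier frequencies, the delay law *and* all four exponents,
  giving the controlled domain shift the evaluation protocols need.
* **Nuisance.** Per-channel white noise at configurable SNR (default
  20 dB; the pressure channel 40 dB, reflecting a catheter's much cleaner
  signal), and a 5% fraction of beats overwritten with high-amplitude
  artifact bursts, flagged in the ground truth, to exercise quality
  screening.

What the simulator does *not* emulate: pharmacokinetic realism, anesthesia
effects, respiration and baseline wander, probe-contact drift, arrhythmia,
or species-specific waveform morphology. Passing end-to-end tests on this
data shows that the pipeline is wired correctly and that the network can
extract amplitude/delay-coded information at realistic SNR — not that the
estimator reaches any particular accuracy on real animals or humans.

## Numerical and design choices

* Filter family and order are unspecified in the protocol the package
  follows; 4th-order Butterworth applied forward–backward is the standard
  biosignal choice and is recorded in `filter_specs()`.
* The quality-screening algorithm and thresholds are the package's own
  (template correlation at 0.8 with flat-line and clipping guards), since
  only the *existence* of automatic removal is specified.
* SBP is read as the cycle's pressure maximum. "End of the systolic
  stroke" could alternatively mean pressure at aortic-valve closure; the
  maximum is consistent with the magnitudes reported for this kind of
  data and is the less ambiguous definition.
* The 3-SD spike rule is implemented with robust scale estimates (see
  above) because the literal moment-based rule cannot flag isolated spikes
  in short records; it is applied per record, the more conservative of the
  two possible scopes.
* Dropout rate (0.2), Adam, and the 1×1 shortcut projection are standard
  choices where the architecture description is silent.
* Training drops incomplete trailing mini-batches; with fewer samples than
  one batch, the whole set forms a single batch.

## Problem sizes used by the tests and the acceptance script

Training this architecture on one CPU costs about 1.6 s per 64-beat batch,
which sets the simulation sizes the package uses for its own end-to-end
validation. The within-subject five-fold run uses 6 records × 85 beats per
record and 30 training epochs per fold; the cross-subject and calibrated
runs train on a second subject with 4 records × 55 beats — differing from
the first in surface couplings, baseline hemodynamics and drug
responsiveness, as real subjects do — and evaluate a single (unswapped)
pass of each protocol for the ordering comparison. These are deliberately
scaled-down studies: they keep the full suite reproducible in minutes
while leaving enough signal range (≈100 mmHg of SBP excursion per record)
for correlation-based comparisons to be meaningful. The QRS benchmark uses
300 noisy beats at 20 dB SNR; label-recovery checks use 1000 analytic
beats spanning the pooled parameter ranges.

## Known limitations

* The estimator learns the simulator's couplings when trained on synthetic
  data; nothing here validates transfer to real recordings.
* MRR above ≈8000 mmHg/s is compressed by the 20 Hz pressure low-pass (a
  few percent), as it would be on any acquisition chain with that filter.
* Heart rates below 60 bpm exceed the 1 s model window and are excluded
  rather than estimated.
* The QRS detector assumes dominant positive R-waves; it is not an
  arrhythmia-grade delineator.
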