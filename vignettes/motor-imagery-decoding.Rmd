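---
title: "Decoding motor-imagery EEG with WPD-CSP-LSTM and EEGNet-LSTM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor-imagery EEG with WPD-CSP-LSTM and EEGNet-LSTM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midecoder)
```

## The decoding problem

Imagining a movement modulates sensorimotor EEG rhythms: band power in
the mu (8–13 Hz) and beta (15–30 Hz) ranges is attenuated or enhanced
over different cortical patches depending on which movement is imagined
(event-related desynchronization/synchronization). A motor-imagery
decoder maps an epoched multichannel trial to one of a small set of
imagined movements. This package implements two such decoders plus the
machinery around them: preprocessing, a synthetic data generator, an
exhaustive hyperparameter grid search, and the statistics used to
compare decoding methods across subjects.

## Preprocessing

Trials pass through a fixed pipeline in the order *filter → crop →
scale*:

* **Bandpass filter.** Zero-phase (forward–backward) Butterworth of
  order 4. The order and design are the package's choice — standard
  EEG practice, deterministic, no group delay; the passband is
  configurable (typical choices: 0.5–100 Hz broadband, 8–13 Hz mu,
  15–30 Hz beta, 8–30 Hz combined, 0.5–45 Hz).
* **Notch.** A second-order IIR notch (quality factor 30, also run
  forward–backward) suppresses power-line interference, typically at
  50 Hz; it is applied only when emulating recordings contaminated by
  mains noise.
* **Cropping.** A half-open window `[tStart, tEnd)` with 0-based sample
  indexing keeps `round((tEnd − tStart) · fs)` samples — e.g. the 2–6 s
  imagery window of a 7.5 s trial at 250 Hz keeps exactly 1000 samples.
* **Scaling.** Min–max to [−1, 1] *per trial and channel* (constant
  channels map to zeros). Scaling scope is deliberately per-trial: a
  global or per-session scale would leak amplitude information across
  trials; the choice is recorded here because only the target range is
  standard.

Labels are one-hot encoded (class *k* → unit vector *e\_k*). Real
continuous recordings can be read from EDF and epoched at supplied
event markers; trials whose window runs past the recording are dropped
with a warning. GDF is recognized but not parsed.

## WPD features

`wpdDecompose()` implements the packet recursion — both the
approximation and the detail branch are filtered and downsampled at
every level — with orthonormal Daubechies filters under periodization,
so the transform conserves energy exactly on even-length signals (the
test suite asserts Parseval to 1e-8 and checks the coefficients against
an independently computed reference). Choices worth knowing:

* **Wavelet family**: Daubechies-4 (8 taps) by default; db1 and db2 are
  available. The family is a free parameter of the method — db4 is a
  common EEG default with enough regularity for smooth band splits.
* **Node indexing**: children `2j` (low-pass) and `2j+1` (high-pass),
  zero-based. The leaf sequence handed to the LSTM uses *frequency
  order* (the binary-reflected Gray-code permutation of the natural
  order, accounting for spectral mirroring at each downsampling), so
  step *s* of the sequence corresponds to the *s*-th frequency band.
* **Odd lengths** are handled by repeating the final sample before each
  split, so leaf lengths equal the trial length divided by `2^level` up
  to small boundary slack.

## CSP features

`cspFit()` follows the classical construction: per-trial spatial
covariances are trace-normalized and averaged per class (`R_H`, `R_F`),
the composite `R = R_H + R_F` is eigendecomposed, trials are whitened
with `P = D^{-1/2} U0'`, and the whitened first-class covariance
`S_H = P R_H P'` is eigendecomposed with eigenvalues sorted descending
(ties keep their original order). Because `S_H + S_F = I`, a direction
with large first-class eigenvalue necessarily has a small second-class
one; the projection `W = U' P` therefore concentrates discriminative
variance in its first and last rows, of which `nPairs` from each end
are retained. Features are `log(var_i / sum(var))` of the projected
rows — invariant to global trial scaling. Numerical choices:

* diagonal loading `eps · trace/C · I` with `eps = 1e-9` before
  decomposition (leaf-node coefficient sequences are short, so sample
  covariances can be near-singular);
* a rank-deficiency error if the composite covariance is singular even
  after loading;
* every intermediate (`P`, `U0`, `D`, `U`, `D_H`, `D_F`) is stored on
  the fitted object so the identities `D_H + D_F = I`,
  `P R P' = I` and the simultaneous diagonalization of both class
  covariances can be verified on any fit.

**Multiclass extension.** The construction is inherently two-class; for
more classes one bank is fitted per class against the rest
(one-vs-rest), the standard extension in filter-bank CSP pipelines.

**Sequence semantics.** How WPD and CSP combine into an LSTM input is
the key interpretive choice of the pipeline: here a separate CSP bank
is fitted *per leaf node*, and the 16 frequency-ordered leaves form the
sequence axis, giving each trial a fixed-length sequence of
`pairings × 2·nPairs` features per step. Fitting happens once, on
training data only; the transform is stateless.

## The decoders

**LSTM head.** Two LSTM layers (standard cell equations: sigmoid
forget/input/output gates over `[h_{t−1}, x_t]`, tanh candidate,
`c_t = f⊙c_{t−1} + i⊙c̃_t`, `h_t = o⊙tanh(c_t)`), each followed by
batch normalization and dropout, then a dense softmax readout. The
default size is 32 units per layer. The package ships a scalar
reference cell in the concatenated-weight parameterization alongside
the batched training layer (separate input/recurrent matrices, fused
gate matmuls); their agreement over random steps and sequences is part
of the test suite. Batch normalization of the sequence-returning layer
is applied per feature over the flattened batch × step axis — the
treatment of the step axis is unstandardized, and this choice keeps
statistics well-estimated for short sequences.

**EEGNet blocks.** Block 1: temporal convolution (`F1` filters, kernel
`1 × LK`, same padding, linear, no bias) → batch-norm → depthwise
spatial convolution across channels (`D` filters per temporal map,
kernel `C × 1`, valid, max-norm 1 constraint as in the original
EEGNet — its omission from some descriptions notwithstanding,
configurable off) → batch-norm → ELU → average-pool `1 × 4` → dropout.
Block 2: separable convolution (`F2` filters, kernel `1 × 16`, same) →
batch-norm → ELU → average-pool `1 × 8` → dropout. Pooling uses integer
floor division, so the pooled time axis has `T %/% 32` steps and the
flattened feature length is `F2 · (T %/% 32)` — 496 for 22 channels ×
1000 samples with `F2 = 16`.

**EEGNet-LSTM.** The pooled block output is reshaped so time becomes
the sequence axis (`T %/% 32` steps × `F2` features) and fed to the
same two-layer LSTM head. `T < 32` is rejected (empty sequence).

**Training.** Softmax cross-entropy (the loss implied by one-hot labels
and a softmax readout), with L2 penalties applied to LSTM kernels and
the dense readout only; optimizers Adam, RMSprop and plain SGD (no
momentum) with standard defaults; fixed epoch counts, no early
stopping. All randomness — weight initialization, shuffling, dropout —
derives from explicit seeds, so training is bit-reproducible.
`trainDecoder()` never mutates its input model and aborts with a
diagnostic if the loss becomes non-finite.

## Hyperparameter search

`gridSearch()` enumerates the full Cartesian product of a grid in
deterministic order (first axis fastest) and evaluates every
configuration exactly once. The shipped grids are the two-stage
protocol: a *common* stage over optimizer × learning rate
{1e-4, 1e-3, 1e-2} × batch size {32, 64, 128} × L2 {0.1, 0.2, 0.3} ×
dropout {0.1, 0.2, 0.3} × epochs {100…1000} (1458 configurations) with
the architecture fixed, then a *specific* stage over LSTM layer sizes
{32, 64, 128, 256}² (16) or the EEGNet axes LK/F1/F2/D (256). The
winner maximizes kappa, with ties broken by accuracy and then
enumeration order (the tie rule is the package's own — both metrics are
recorded, no rule is standard). Tuning uses a stratified 30% holdout of
the training data (`holdoutSplit()`), or a designated tuning subject
whose selected configuration is frozen for the rest — both protocols are
exposed, including the leak-free holdout variant.

## Evaluation statistics

* **Accuracy** and multiclass **Cohen's kappa**
  `(p_o − p_e)/(1 − p_e)` with `p_e` from marginal products; kappa is
  the standard motor-imagery competition metric because it corrects
  for class-count differences. Constant, identical inputs define
  kappa = 1.
* **Paired Wilcoxon signed-rank**, pinned to one variant: zero
  differences discarded, midranks for tied `|d|`,
  `Z = (W⁺ − n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 − Σ(t³−t)/48)`, two-sided
  normal p, **no** continuity correction. `|d|` is rounded to 10
  decimals before ranking: score tables carry 2-decimal values, and
  binary floating point would otherwise hide exact ties (0.85 − 0.70
  and 0.69 − 0.54 differ at the 17th digit), changing the tie
  correction and hence Z in the third decimal. An exact
  sign-enumeration p-value is available for n ≤ 20.
* **Summaries** use the arithmetic mean and the n−1 sample standard
  deviation; rounding (2 decimals for kappa, 3 for Z and p) is applied
  only for display.

The bundled per-subject kappa table (six methods, eight subjects)
reproduces, via these functions, the means 0.81 / 0.63 / 0.58 / 0.67 /
0.64 / 0.64, the 0.109 standard deviation, and the Z statistics 2.524,
2.371, 2.028, 2.527 and 1.540 with their p-values — the test suite and
`scripts/acceptance.R` recompute all of them. One published pair (the
EEGNet-LSTM vs FBSF-TSCNN narrative value Z = 2.527 with p = 0.018) is
internally inconsistent — no standard normal-approximation variant maps
that Z to that p, and neither emerges from the table row, which gives
Z = 2.366, p = 0.018; the package reports the recomputed value.

## The synthetic generator

`generateEpochs()` emulates the statistical structure the decoders
exploit: per class, band-limited Gaussian noise (an ideal FFT-domain
bandpass of white noise — a stochastic rhythm rather than a pure tone,
because CSP discriminates variance and a deterministic sinusoid would
make the task degenerate) is projected through a class-specific
unit-norm spatial pattern and added to i.i.d. Gaussian broadband noise.
`snr` is the ratio of total rhythm power (over channels) to per-channel
noise power; `snr = 0` yields pure noise. Default geometry follows a
standard four-class recording (72 trials/class, 22 channels, 250 Hz,
7.5 s); class band centers spread over 10–26 Hz with 4 Hz bandwidth,
and default mixing patterns are a seed-derived orthonormal set, which
guarantees CSP-recoverable structure. Generation is a pure function of
the configuration including its seed.

What it does **not** model: eye-blink/EMG artifacts, volume-conduction
head geometry, non-stationarity across a session, inter-subject
variability, 1/f background spectra. Passing tests on this generator
demonstrate that the pipeline recovers class-dependent band-power
structure under controlled conditions — not that the decoders reach any
particular accuracy on real recordings.

## Problem sizes used in the checks

The end-to-end checks train both decoders on 2-class data with 120
trials per class, 8 channels, 128 Hz, 2 s trials (the window length is
the package's choice of a typical cropped imagery segment) at snr = 5,
with a stratified 30% holdout: the EEGNet-LSTM (F1 = 8, D = 2,
F2 = 16, LK = 32, 32-unit LSTM layers) trains for 25 epochs and the
WPD-CSP-LSTM decoder for 30; both reach their held-out accuracy targets
with a wide margin. Chance-level behaviour is verified on snr = 0 data
from the same geometry. Full-scale grid searches (1458 configurations ×
long training) are enumerated against a mock trainer; actually training
that grid is a compute-cluster exercise, not a package test.

## Known limitations

* The deep-learning core is a deliberately small, deterministic CPU
  implementation; it is suitable for the package's problem sizes, not
  for large-scale GPU training.
* GDF recordings are not parsed; convert to EDF or epoch externally.
* Multiclass CSP is one-vs-rest only; no Riemannian or adaptive
  variants.
* The Wilcoxon p-values use the normal approximation by default, which
  is what the comparison tables in this literature report; for n < 10
  the exact mode is the statistically safer choice.
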