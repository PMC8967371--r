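---
title: "Methods: the eegstn spatiotemporal EEG emotion-recognition pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the eegstn spatiotemporal EEG emotion-recognition pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegstn)
```

# The problem

Cross-subject — and, harder still, cross-database — emotion recognition
from scalp EEG suffers from a basic distribution-shift problem: different
people (and different recording set-ups) produce multichannel signals with
different second-order spatial statistics, so a classifier trained on one
group of subjects degrades badly on a new one. `eegstn` implements a
complete pipeline that addresses this with three ingredients:

1. **Euclidean alignment (EA)** — an unsupervised per-subject whitening
   that equalises average spatial covariance across subjects;
2. **time–frequency band-energy features** computed two ways (short-time
   Fourier transform, and the Hilbert–Huang transform built on empirical
   mode decomposition), mapped onto a 2-D electrode-topology grid so that
   scalp geometry is preserved;
3. a **cascaded 2-D CNN + bidirectional LSTM** that learns spatial
   structure within each one-second frame and temporal structure across a
   sequence of frames.

Everything is exercisable on synthetic EEG with known ground truth; no
external recordings are required.

# Pipeline stages and their assumptions

## Preprocessing

Raw trials (channels x samples, microvolts) are band-pass filtered with a
windowed-FIR design: Hamming window, order 50 (51 symmetric taps), pass
band 1–50 Hz. A linear-phase single-pass FIR is the standard choice for
EEG because it does not distort wave phases; we compensate the constant
group delay of `order/2` samples explicitly and pad edges by signal
reflection, so the output stays sample-aligned with the input
(`apply_filter()`). Two numerical facts worth knowing:

* a 51-tap design at 200 Hz has a transition band of roughly 13 Hz, so the
  nominal 1 Hz low edge attenuates very slow drift only mildly (about
  −2.4 dB at 0.2 Hz). This is a property of the specified order, not a
  defect of the implementation; `filter_response()` exposes the exact
  transfer function and the tests assert against it.
* the stop band beyond the transition (e.g. 75 Hz) is attenuated by well
  over 20 dB.

All databases are brought to a common 200 Hz by polyphase rational-ratio
resampling (`resample_recording()`), *regardless of direction* — a 100 Hz
database is upsampled. The recordings are then cut into consecutive,
non-overlapping one-second epochs, the pipeline's atomic sample; a
trailing remainder shorter than one epoch is discarded rather than padded.

## Euclidean alignment

For each scope (by default each subject–session), with epochs
$X_n \in \mathbb{R}^{c \times t}$:

$$\bar R = \frac{1}{N}\sum_{n=1}^{N} \frac{X_n X_n^\top}{t}, \qquad
  \tilde X_n = \bar R^{-1/2} X_n .$$

After the map, the scope's mean sample-normalised covariance is the
identity, so all subjects share their average second-order statistics.
Design choices:

* **Sample normalisation by `t`.** The classical formulation omits the
  `1/t`; it is a global scalar that the inverse square root absorbs, and
  carrying it keeps the "mean covariance = identity" invariant in natural
  units. The whitened signal is identical either way up to a constant
  factor, which the relative band energies cancel exactly.
* **Scope.** Alignment per subject–session by default (configurable to
  per subject) because session structure differs across databases.
* **Conditioning.** `inv_sqrtm()` floors eigenvalues at
  $10^{-10}\lambda_{max}$; an optional shrinkage
  $(1-\lambda)\bar R + \lambda\,\overline{\mathrm{diag}}\,I$ (default
  $\lambda = 0$) is available for rank-deficient scopes.
* EA is computed on filtered, epoched data and is fully unsupervised, so
  in the cross-database protocol each side is aligned with its own
  references — no information crosses the train/test divide.

Useful invariants (all tested): whitening to identity within $10^{-6}$
relative Frobenius norm; idempotence (re-aligning aligned data is a
no-op); scale equivariance (scaling a scope's data leaves the aligned
output unchanged).

## Time–frequency features

Per epoch and channel the pipeline computes the relative energies of the
five classical rhythm bands — delta 1–4, theta 4–8, alpha 8–14, beta
14–30, gamma 30–50 Hz — under one of two spectra:

* **STFT** (`stft_spectrum()`): Hann window of `fs/2` samples with 50%
  overlap, squared magnitude. A half-second window gives 2 Hz resolution,
  enough to resolve delta inside a one-second epoch. The one-sided
  spectrum is normalised so total mass equals windowed signal energy
  (Parseval, tested to 1%).
* **HHS** (`emd()` + `hilbert_spectrum()`): standard sifting with
  cubic-spline envelopes through maxima/minima (up to two extrema
  mirrored across each boundary), Huang's SD criterion < 0.2 or at most
  10 sifts per IMF, at most 8 IMFs, stopping when the residual has fewer
  than three extrema. These are the canonical defaults. The decomposition
  is exactly additive by construction. Each IMF's analytic signal yields
  instantaneous amplitude and frequency (central differences on the
  unwrapped phase); $A_k^2(t)$ is accumulated at $(t, f_k(t))$ over 0.5 Hz
  bins, and samples with instantaneous frequency outside 1–50 Hz are
  dropped from numerator *and* denominator.

"Relative energy" is normalised per channel across the five bands, so each
channel's shares sum to one and a 62-channel epoch yields
$5 \times 62 = 310$ features. The normalisation makes features invariant
to per-channel amplitude scaling — which is also why Euclidean alignment
matters at the feature level only through cross-channel *mixing*, not
through gains. Band membership of a spectral bin is half-open
(`low <= f < high`, upper edge of gamma inclusive). One caveat the tests
document: with the default half-second window a 2 Hz tone leaks roughly
half its mass into the excluded DC bin (Hann main-lobe width), so
delta/beta symmetry of an equal-power 2 + 20 Hz pair only appears once the
window resolves the slow tone (e.g. a full-epoch window).

## Spatial tensorisation

Scalp geometry is reinstated by mapping the 310 features onto a 9 x 9
grid following the cap's topology: 62 cells carry electrodes, 19 are
structural zeros, and the five band slices stack into a
$9 \times 9 \times 5$ tensor per epoch (`default_montage_62()`,
`tensorize()`). Placement is keyed by electrode *name*, so channel order
is irrelevant; `detensorize()` is the exact inverse on placed cells.
Other caps (e.g. a 128-channel montage on a 21 x 19 grid) are supported
through a JSON montage file — they are deliberately not hard-coded, since
grid layouts are lab conventions, not universal standards.

## The spatiotemporal classifier

Each frame passes through five same-padded 3 x 3 convolutions with ReLU
(filter counts 32, 64, 128, 128, 64 by default), a flatten, and a fully
connected ReLU layer to a 256-dimensional "global spatial" embedding.
The sequence of `T = 12` consecutive frame embeddings (12 s, windows
never spanning trials, remainders discarded) feeds a bidirectional LSTM
with 128 hidden units per direction; the final states of both directions
are concatenated and mapped by a fully connected softmax layer to class
probabilities. Training is bare mini-batch SGD (batch 32, no momentum, no
dropout, no weight decay), cross-entropy loss, and the stepped schedule

$$lr(e) = 0.005 \times 0.95^{\lfloor e / 10 \rfloor}.$$

The five-layer 3 x 3 structure, frame length, batch size, schedule and
optimiser are the pipeline's fixed conventions; filter counts, embedding
width and LSTM size are free parameters chosen for the 9 x 9 input and
exposed in `stn_model_spec()`. The implementation is plain R on BLAS:
convolution is computed as nine shifted matrix products, and all
gradients are hand-derived (verified against numerical differentiation
during development). Training is bit-reproducible under a fixed seed;
prediction is deterministic.

## Evaluation protocols

* `cross_database_protocol()`: train on one dataset, test on a disjoint
  one; label vocabularies are harmonised first (happy → positive,
  sad → negative); each side aligned with its own EA references.
* `loso_protocol()`: one fold per held-out subject; per-subject accuracy
  and weighted F1, plus their unweighted mean and standard deviation.
  Features are computed once (EA is per-subject and unsupervised, so this
  leaks nothing); each fold refits with a subject-derived seed, making
  results independent of enumeration order.
* `subject_kfold()`: subject-level (never epoch-level) stratified k-fold
  for the depression design; with 24 patients + 29 controls and k = 5 the
  fold sizes are 11, 11, 11, 11, 9 (four folds of 5 + 6 and one of
  4 + 5). Note the arithmetic: any description of such a split as "three
  folds of 11 and one of 9" cannot cover 53 subjects; the partition here
  is the unique stratified one with fold sizes differing by at most one.
* `frame_length_sweep()`: reassembles sequences and retrains for frame
  lengths 8–32 in steps of 4 (skipping lengths longer than every trial),
  reporting accuracy and weighted F1 per length.
* `compute_metrics()`: accuracy (percent), support-weighted F1, and a
  confusion matrix with true labels on rows.

Accuracy is accounted per sequence (one label per `T`-frame window).
Per-epoch accounting can be recovered by broadcasting the sequence label,
but the sequence is the unit the classifier actually decides on.

# The synthetic generator

`synth_spec()`/`generate_dataset()` emulate the structure the pipeline
needs to be testable: multiple subjects, classes with distinct band-power
signatures, and subject-specific covariance shift.

* **Oscillators.** One sinusoid per band at the band's geometric-centre
  frequency, with an independent random phase per trial and channel;
  class profiles set per-band amplitudes (defaults: 2.5 uV in the
  dominant band — alpha for "positive", theta for "neutral", beta for
  "negative" — against a 0.6 uV baseline). Centre-frequency sinusoids
  make band-energy ground truth analytic.
* **Band topographies.** Each band's amplitude is modulated by a fixed
  smooth spatial profile across channels (range 0.6–1.4). This is not
  decoration: per-channel *relative* band energies are invariant in
  expectation to channel mixing when every channel has the same band
  composition, so without a topography the subject-mixing perturbation
  would not reach the features and an EA ablation would be vacuous.
  Real EEG rhythms are spatially structured for the same reason the
  caricature works (alpha posterior, frontal theta, and so on).
* **Subject covariance shift.** Each subject owns a fixed mixing matrix
  $A_s = I + s\,P/\sqrt{C}$ with standard-normal $P$ drawn once from a
  subject-specific sub-stream; all the subject's trials are premultiplied
  by it. If $X_s = A_s X_0$, whitening removes $A_s$ up to an orthogonal
  factor, which is exactly the regime EA targets.
* **Noise.** I.i.d. Gaussian per channel (default 1 uV) — the simplest
  null for spectral tests.
* **Determinism.** Every draw comes from a sub-stream keyed on the spec
  seed and the entity (subject, trial), so the same spec is bit-identical
  across runs and any stage can be rerun in isolation.

What the generator does *not* emulate: 1/f background spectra, artifacts
(blinks, EMG), volume conduction, non-stationarity within trials, or any
physiological coupling between bands. Passing tests therefore demonstrate
the pipeline's *mechanics* — whitening, spectral estimation, geometry,
optimisation, protocol bookkeeping — not performance on real EEG.

# The default benchmark

The end-to-end benchmark (`benchmark_config()`) uses 4 subjects (3 train,
1 held out), 3 classes, 4 trials per class per subject, 12 s trials at
200 Hz over the 62-channel montage, mixing strength 0.3, 1 uV noise, STFT
features, the default architecture and 30 training epochs. These sizes
keep a full run (with its EA-ablation twin) to a few minutes on one CPU
core while leaving 12 held-out sequences to score. At this
signal-to-noise ratio the task is deliberately easy: the check is that
the pipeline *learns* (accuracy far above the 33.3% chance level within
30 epochs) and that alignment never hurts — both arms can and do
saturate, so the EA comparison is a direction, not an effect size.

# Numerical choices, degenerate inputs, tie-breaks

* Eigenvalue floor $10^{-10}\lambda_{max}$ in `inv_sqrtm()`; symmetric
  inputs enforced to an $10^{-8}$ relative tolerance.
* All-zero epochs produce all-zero band shares (not NaN); they simply do
  not normalise to one.
* EMD of a constant signal returns zero IMFs with the input as residual;
  signals shorter than 10 samples are rejected.
* `max.col(..., ties.method = "first")` makes argmax predictions
  deterministic under exact probability ties.
* Epoching and sequence assembly discard trailing remainders; nothing is
  ever padded with fabricated samples.
* Resampling requires rates expressible as a rational ratio (after
  scaling by up to 10^6), which covers any realistic EEG rate pair.

# Known limitations

* The generator's caricature means benchmark accuracies say nothing about
  accuracies attainable on real emotion or depression datasets.
* The EA ablation on the default benchmark is a one-sided sanity check;
  measuring a *gap* requires harder conditions (stronger mixing, lower
  SNR) at correspondingly longer runtimes.
* The HHS path is substantially slower than STFT (sifting is per channel
  and nonlinear) and is the non-default method for the large benchmark.
* The CNN/BiLSTM runs on CPU BLAS; it is sized for method validation, not
  for training on hundreds of thousands of real epochs.
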