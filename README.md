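# eegstn

A spatiotemporal neural-network pipeline for cross-subject and
cross-database EEG emotion recognition, with an application profile for
EEG-based depression screening. The package is aimed at BCI /
affective-computing researchers who need the full chain — preprocessing,
subject alignment, time–frequency features, topology-aware tensorisation,
classification and protocol-correct evaluation — as tested, reproducible
building blocks that run on synthetic EEG with known ground truth.

## The method

Cross-subject transfer fails on EEG mostly because subjects differ in
their spatial second-order statistics. The pipeline counters this with
**Euclidean alignment**: for each subject (scope), with epochs
`X_n ∈ R^{c×t}`,

    R̄ = (1/N) Σ_n X_n X_nᵀ / t        (mean spatial covariance)
    X̃_n = R̄^{-1/2} X_n               (whitening)

after which every subject's average covariance is the identity. Aligned
epochs are reduced to **relative band energies**: per channel, the share
of time–frequency power in delta (1–4), theta (4–8), alpha (8–14), beta
(14–30) and gamma (30–50 Hz), computed either from a Hann-window STFT or
from the Hilbert–Huang spectrum (EMD sifting + per-IMF instantaneous
amplitude/frequency). A 62-channel epoch gives 5 × 62 = 310 features
`s_f^c`, which are placed on a 9 × 9 electrode-topology grid (empty cells
zero) to form a `9 × 9 × 5` tensor per epoch. Sequences of `T = 12`
consecutive tensors feed a cascaded classifier: five 3 × 3 ReLU
convolutions → fully connected spatial embedding → bidirectional LSTM →
softmax, trained with bare SGD (batch 32, cross-entropy,
`lr(e) = 0.005·0.95^⌊e/10⌋`). Evaluation protocols cover cross-database
transfer, leave-one-subject-out, subject-stratified k-fold (the
24 + 29 → 11/11/11/11/9 depression design) and a frame-length sweep.

The CNN+BiLSTM (including backpropagation) is implemented in base R on
BLAS; no deep-learning framework is required. A synthetic multi-subject
generator with class-specific band signatures and per-subject covariance
shift makes every stage testable end to end.

## Worked example

```r
library(eegstn)

## 1. synthesise a small labelled multi-subject dataset
spec  <- synth_spec(n_subjects = 3, n_trials_per_class = 2,
                    trial_duration = 8, seed = 42)
recs  <- generate_dataset(spec)
recs[[1]]
#> <eeg_recording> sub01/ses1/sub01_c1_t01: 62 ch x 1600 samples @ 200 Hz (8.0 s), label=positive

## 2. preprocess: 50-order 1-50 Hz FIR, cut into 1-s epochs
filt   <- design_bandpass(1, 50, 50, fs = 200)
epochs <- epoch_recordings(lapply(recs, apply_filter, filt))
epochs
#> <eeg_epochs> 144 epochs x 62 ch x 200 samples @ 200 Hz; 3 subject(s), 18 trial(s)

## 3-4. align, extract band features, tensorise
aligned <- ea_align(epochs)
tfs     <- extract_tfs(aligned, method = "stft")
tfs
#> <tfs_matrix> STFT: 144 epochs x 62 channels x 5 bands (310 features/epoch)
```

Each printed shape is meaningful: 18 trials of 8 s give 144 one-second
epochs; each epoch carries the 310 `s_f^c` features (five band shares per
channel, each channel's shares summing to 1); `tensorize()` would map
them onto 9 × 9 × 5 grids with 62 occupied cells.

The packaged end-to-end benchmark (4 subjects — 3 train, 1 held out — 3
classes, 30 training epochs; a few minutes on one CPU core):

```r
res <- run_pipeline(benchmark_config(seed = 1))
print(res)
#> <stn_pipeline_result> config 2e006fa2, seed 1 (with EA)
#> <eval_report> [cross_subject] accuracy 100.00%, weighted F1 1.000 (n = 12)
#> confusion (true rows x predicted cols):
#>           predicted
#> true       negative neutral positive
#>   negative        4       0        0
#>   neutral         0       4        0
#>   positive        0       0        4
```

The held-out subject's 12 sequences are classified perfectly: the
generator's band signatures are strong, and per-subject whitening removes
the simulated covariance shift, so the spatiotemporal network separates
the three classes well above the 33.3% chance level. Running the same
configuration with `benchmark_config(seed = 1, align = FALSE)` gives the
"without EA" ablation arm.

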