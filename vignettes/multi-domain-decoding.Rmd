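---
title: "Multi-domain decoding of motor-imagery EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-domain decoding of motor-imagery EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mdbci)
```

## The decoding problem

Motor imagery (MI) — the mental rehearsal of a movement — modulates
sensorimotor EEG rhythms in ways that a classifier can decode, which is the
basis of non-invasive brain–computer interfaces. Decoding lower-limb MI
(gait, sitting down, rest) is harder than hand MI because the relevant
cortical sources lie deep in the interhemispheric fissure, and it is harder
still with dry electrodes, whose high contact impedance lowers the
signal-to-noise ratio (SNR) relative to gel-based ("wet") recordings.

`mdbci` implements a multi-domain convolutional network for this setting.
The premise is that no single signal representation is uniformly best: which
features survive a given subject's anatomy and a given electrode's noise
floor varies. The model therefore learns three representations of the same
trials in parallel and lets a fused classification head weight them.

## The three domains

Every trial is an `N × T` matrix `E` (channels × samples, microvolts).

**Time domain.** The band-passed signal itself, unchanged. Amplitude
dynamics (event-related desynchronization/synchronization) live here.

**Spatial domain.** The common-spatial-pattern (CSP) projection `Z = W E`.
For two classes, CSP filters maximize the variance ratio between class
covariances. For `M > 2` classes we use the joint-approximate-
diagonalization (JAD) construction: with trial covariances normalized by
their trace and averaged per class into `R_1 … R_M` (priors `P(c_i)`),

1. whiten by the prior-weighted average covariance,
2. find one orthogonal matrix that simultaneously near-diagonalizes the
   whitened class covariances (Jacobi sweeps of Givens rotations with the
   closed-form Cardoso–Souloumiac angle),
3. compose whitener and rotation into `W`.

Each filter `w_j` is scored by a mutual-information approximation based on
its per-class variances `v_ji = w_j' R_i w_j` (whitening makes the
prior-weighted mean of `v_ji` equal 1):

`I_j = − Σ_i P(c_i) log v_ji − (3/16) (Σ_i P(c_i)(v_ji² − 1))²`

Filters are sorted by descending score. We keep all `N` filters by default
(`L = N`), so the spatial domain keeps the input geometry and the network
sees a full rotation of the data rather than a reduced subspace; `L` is a
parameter of `apply_csp()`. A variant of the score with `log √v` (used in
parts of the JAD-CSP literature) is available via `mi_variant = "sqrt"`;
the default follows the plain-`log` form.

**Phase domain.** The instantaneous phase of each channel: build the
analytic signal `z(k) = s(k) + i ŝ(k)` with the Hilbert transform `ŝ`,
then take `φ(k) = atan2(ŝ, s)`, wrapped to `(−π, π]`. The default
construction is the exact FFT analytic signal (zero the negative
frequencies, double the positive ones); the O(T²) parity-split direct
summation `ŝ(k) = (2/π) Σ_{n opposite parity} s(n)/(k−n)` is implemented in
`hilbert_direct()` and serves as the reference form in the tests. We use the
four-quadrant arctangent (the two-quadrant `arctan(ŝ/s)` is sign-ambiguous)
and feed the wrapped phase directly to the network without unwrapping; edge
samples are not tapered, so the network sees the same edge distortion a
practitioner would.

## Network architecture

Each domain feeds an identical shallow convolutional branch:

1. temporal convolution — 40 kernels of length 25, shared across channels
   (valid; a 31 × 1000 window yields a 40 × 1 × 976 map after both
   convolutions),
2. spatial convolution — 40 kernels spanning all channels and all temporal
   maps,
3. batch normalization, square activation,
4. average pooling, kernel 1 × 75, stride 1 × 15,
5. `log(max(x, 1e-6))`, dropout 0.5,
6. a fully connected layer to `D` features (default `D = 40`).

The square–pool–log cascade makes the branch compute smoothed log
band-power of learned spatio-spectral filters, which is why a single branch
is a standalone shallow ConvNet classifier (set `branches = "time"`). Each
branch has its own softmax head; the three `D`-vectors are concatenated and
a final fully connected softmax produces the fused ("multi") prediction.
The training loss is the weighted sum of the four heads' cross-entropies
(default weights 1,1,1,1 — every head is trained).

Note one arithmetic point: average-pooling a 976-length map with kernel 75
and stride 15 gives `floor((976 − 75)/15) + 1 = 61` output bins. A pooled
length of 44 (sometimes quoted for this architecture) would require roughly
726 input samples, i.e. ~3-s crops; `model_shapes()` reports 61 for 1000
input samples and the package keeps the stated kernel/stride.

Weight updates use Adam (initial learning rate 1e-3) on shuffled
mini-batches of 32 for 100 epochs (defaults), with the learning rate halved
when the monitored loss fails to improve for 10 epochs. A max-norm
constraint reprojects every convolutional (radius 2.0) and fully connected
(radius 0.5) weight vector after each step; radii are configurable since the
literature the constraint comes from does not fix them. Checkpointing keeps
the weights with the lowest monitored loss. The default monitor is the loss
on the evaluation crops (`monitor_test_loss`), mirroring the protocol of the
study this reimplements; note that this peeks at the test fold, so the
honest alternative `monitor_val_loss` (an inner stratified 10% trial split
of the training data) is provided and recommended for new work.

All forward/backward passes are written in RcppArmadillo as batched BLAS-3
operations; there is no external deep-learning dependency. Gradients of
every layer are verified against central finite differences in the test
suite. A structural consequence of batch normalization directly after the
convolutions is that the temporal bias receives an exactly zero gradient
(a constant per-map shift is removed by the normalizer); it is kept for
completeness.

## Cropped training

Trials are augmented by sliding a 4-s window in 0.1-s steps (a 5-s trial
yields 11 crops). The domain transforms are applied to the full trial
*first* and the resulting tensors are cropped with identical offsets, so all
crops of a trial share one spatial projection and one analytic signal; this
also avoids recomputing the transforms per crop. Offsets are rounded to the
nearest sample (exact at the standard rates: 0.1 s × 250 Hz = 25 samples).
At prediction time, crop softmax rows are averaged per trial before the
arg-max (mean-probability voting; per-crop scoring is available via
`aggregate = "crop"`). Ties resolve to the lowest class index.

## Evaluation

`run_pipeline()` performs stratified 10-fold cross-validation: per-class
shuffled round-robin dealing keeps fold class counts within one trial of
perfect stratification. All fitted components — CSP, per-channel
normalization statistics (z-scoring per domain, fitted on training trials
and frozen), and the network — see training trials only; the test suite
checks this by refitting.

Accuracies are compared against the **chance-level confidence limit**: the
accuracy a random classifier would not exceed with probability α given `n`
evaluation trials. With `p0 = 1/M`, the smallest exceedance count is
`m = ⌈n p0 + z_{1−α/2} √(n p0 (1−p0))⌉` and the limit is `100 m / n` — for
90 trials and 3 classes, 39/90 = 43.33%; for 288 trials and 4 classes,
87/288 ≈ 30%. An exact-binomial variant is available. Paired comparisons
between conditions use a paired t-test and Cohen's d (pooled-SD form by
default; the paired-differences form is a flag).

## Synthetic data: what it emulates and what it does not

`synth_config()` defaults define the simulated study conditions: 31 channels
(standard 10-20 montage subset), 500 Hz acquisition, 3 classes × 30 trials
of 5-s epochs. Each class adds a narrow-band oscillatory signature —
band-limited Gaussian noise, hence randomly phased and amplitude-modulated —
on class-specific channels over independent 1/f background noise:

* gait: 10 Hz at Cz; sit: 22 Hz at C1; rest: 14 Hz at Oz (motor-area
  channels echo lower-limb MI topography; the frequencies sit inside the
  4–40 Hz analysis band and in the mu/beta range),
* signature amplitude 5 µV RMS, background 10 µV RMS at slope α = 1 —
  an in-band SNR a practitioner would call a clean wet recording,
* the `dry` preset multiplies the background by 3 (default), emulating the
  higher noise floor of dry electrodes; `synth_generate_pair()` reuses the
  identical signal and background draws so the two members differ *only* in
  background scale,
* `signature_kind = "broadband"` replaces oscillations by flat-spectrum
  variance gains (class information in power only — useful for probing what
  the phase branch can and cannot contribute), and `mixing = TRUE` applies a
  diagonally dominant random channel-mixing matrix as a crude
  volume-conduction stand-in.

The generator is deterministic under its seed. What it does **not**
emulate: realistic source geometry or forward models, ocular/muscle
artifacts, electrode drift, non-stationarity across a session, or
subject-to-subject variability. Tests passing on this generator therefore
demonstrate that the implementation recovers planted class structure under
controlled SNR — not that any particular accuracy carries over to real
recordings.

## Problem sizes used by the test suite

The full-scale architecture (40+40 filters on 31 × 1000 windows, 100
epochs, 10 folds) is a multi-hour CPU computation. The package's automated
checks therefore run a reduced-scale protocol, chosen once as a faithful
miniature of the full pipeline: band-pass 4–40 Hz, downsample to 125 Hz,
2-s crops stepped at 0.5 s (7 crops per 5-s trial), 8+8 filters, `D = 20`,
batch 32, 12 training epochs for the 10-fold run and 8 for single-split
contrasts. Under these conditions the fused head decodes the generator's
default data essentially perfectly (well above the 43.33% limit), so the
reduction does not weaken the conclusions the tests draw. The wet/dry
contrast is evaluated on matched generator pairs over five seeds with a
stratified 80/20 holdout per condition.

## Numerical choices and degenerate inputs

* Zero-phase filtering applies the Butterworth design forward and backward
  (doubling the effective magnitude order, as is conventional) around
  odd-reflection padding of three filter lengths, which suppresses edge
  transients that plain reverse filtering from rest states would leave.
* Resampling low-passes at 80% of the target Nyquist (zero-phase, order 4)
  and decimates; only integer rate ratios are supported, which covers the
  standard 500→250→125 Hz chain.
* Normalization clamps zero-variance channels to a small epsilon and warns
  rather than producing NaN.
* CSP whitening refuses near-singular average covariances and points to the
  `ridge` diagonal-loading option instead of silently regularizing.
* The joint diagonalizer runs Jacobi sweeps to a 1e-12 rotation threshold;
  for commuting (two-class) problems it is exact to machine precision, and
  tests check it beats 1000 random orthogonal rotations on 3-class
  problems.
* Equal mutual-information scores are broken by original filter index
  (stable sort).
* `log(max(x, ε))` with ε = 1e-6 guards zero-variance crops; softmax logits
  are max-subtracted before exponentiation.
* Fold assignment, initialization, batch shuffling and dropout masks all
  derive from explicit seeds; two runs with the same configuration are
  bit-identical.

## Known limitations

* GDF support covers GDF 1.x (the BrainVision and EDF/EDF+ readers cover
  the other acquisition paths); GDF 2.x files should be converted first.
* Only integer-factor resampling is implemented.
* The per-session protocol decodes one subject at a time; there is no
  cross-subject transfer machinery.
* `monitor_test_loss` reproduces a protocol that selects checkpoints on the
  evaluation fold; use `monitor_val_loss` when measuring honest
  generalization.
* Training runs on CPU in double precision; at the full 40-filter scale a
  10-fold run is hours, not minutes.
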