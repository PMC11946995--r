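---
title: "Vibroacoustic pedicle-screw loosening detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibroacoustic pedicle-screw loosening detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pedicle screws anchor spinal instrumentation in the vertebral pedicles.
When a screw loosens, a fan-shaped cavity forms around the shaft and the
implant can toggle relative to the bone. Imaging misses a substantial
fraction of loose implants, and the intraoperative gold standard —
measuring extraction torque — destroys the bone–implant interface of
screws that were in fact tight. `vibroscrew` implements a non-destructive
alternative: excite the vertebra with a sine-sweep vibration at the
spinous process, record the structure-borne response directly at the screw
head with a piezo contact microphone, and classify the propagated
vibration signature as *fixed* or *loose* with a convolutional network.
The package also implements the tracking-based validation statistic used
to confirm that an experimentally loosened screw really moves more than a
tight one, and a seeded synthetic generator for both data modalities so
that the full pipeline is testable without cadaveric recordings.

## Signal chain

### Excitation

The excitation is a 2.5 s sweep from 10 to 500 Hz, sampled at 44.1 kHz and
captured at 24-bit depth. The frequency law is not uniquely determined by
the frequency range alone; we default to a **linear chirp with zero
initial phase** (the simplest reading of a stated frequency range) and
expose an exponential law behind a config flag. Sweep amplitude is
likewise unspecified by the protocol; the default of 0.8 full scale leaves
headroom for resonant gain in the simulated transfer path, so simulated
sensor signals rarely clip.

### Log-mel features

Every recording is mapped to a 256 × 218 log-mel spectrogram:

* short-time Fourier transform with a Hann window, FFT length 2048 and hop
  `H = 256`, with centered (reflection-padded) framing;
* decibel mapping `X_dB = 10 log10(max(|X|, 1e-10)^2)` — an absolute
  reference with an amplitude floor, no peak-relative rescaling and no
  top-dB clipping;
* 256 unit-peak triangular filters with centers equally spaced on the mel
  scale `f_mel = 2595 log10(1 + f/700)` (the HTK-style constant-2595
  variant) between 0 Hz and the analysis Nyquist.

A 2.5 s capture at 44.1 kHz framed with hop 256 would give about 431
frames, not 218. The canonical 256 × 218 feature shape is therefore only reachable
with an additional canonicalization step, which we reconstruct as:
**resample to 22,050 Hz, then trim/zero-pad to 55,552 samples**, so that
centered framing yields exactly `1 + floor(55552/256) = 218` columns. The
analysis band (0–11.025 kHz) still contains the excited range and the
high-frequency loosening signature with a wide margin. This is one
consistent reconstruction, and it is confined to `feature_config()`, so
any other convention can be swapped in.

In the transform sum, the window length (2048) plays the role of the DFT
length; the signal-length symbol in the textbook formula is read as the
window length, as is standard for framed transforms.

Normalization is global standardization `(X - mu)/sigma`. The original
protocol computes the statistics over the *entire* dataset; because that
leaks test information into training, the cross-validator defaults to
`norm_scope = "train_only"` and offers `"entire_dataset"` as the
protocol-faithful option. Augmentation operates on raw waveforms: pitch
shifts drawn uniformly from [-3, 3] semitones (the stated range has no
grid; we read it as continuous) and time stretches with factor
0.9 or 1.1. Time stretching uses a phase vocoder on our own STFT; pitch
shifting resamples and stretches back to length. Augmented copies are
created for training folds only.

### Classifier

`build_model()` assembles an 18-layer squeeze-and-excitation residual
network operating on a single-channel 256 × 218 input:

* stem: 3 × 3 stride-1 convolution + 2 × 2 max pool (the reference
  design uses 3 × 3 filters in every layer, overriding the canonical
  7 × 7 stem);
* four stages of two residual blocks (conv–BN–ReLU, conv–BN, SE, shortcut
  add, ReLU) with filter counts 64/128/256/512 and stride-2 projection
  shortcuts at stage transitions;
* SE blocks squeeze by global average pooling, bottleneck to `C/r` with
  `r = 8`, and gate channels with a logistic; placed after the second
  convolution, before the residual addition (the reference arrangement);
* global average pooling and a single-logit head.

Counting the stem, the 16 block convolutions and the head gives 18
weighted layers. Training uses Adam (`lr = 1e-5`, 10 epochs, binary
cross-entropy) by default; batch size 16 is our choice (unstated in the
protocol). `use_se = FALSE` yields the plain residual network used in the
ablation comparison. The entire network — convolutions via compiled
im2col/GEMM kernels, batch normalization, SE attention, Adam,
backpropagation — is implemented in this package; the forward pass is
deterministic and training is exactly reproducible from `rng_seed`.

### Evaluation

`cross_validate()` performs leave-one-specimen-out cross-validation: one
fold per specimen, the test fold containing every recording (both
sensors, both conditions) of that specimen, and a model trained from
scratch on the rest. Fold metrics use *loose* as the positive class, and
`summarize_folds()` aggregates them as mean ± **population** (denominator
*n*) standard deviation — the convention pinned by the reference cadaveric
experiment, whose per-fold sensitivities {94.00, 81.00, 92.00, 99.00}
aggregate to 91.50 ± 6.58 and specificities {94.00, 87.76, 90.62, 92.00}
to 91.10 ± 2.27; the sample
(n − 1) convention would give ±7.59 and ±2.62. Per-fold accuracy is
computed from that fold's pooled confusion counts and then averaged, the
same handling as sensitivity and specificity.

## Loosening validation statistic

For each screw, an optical tracking system records reference-point
trajectories of vertebra L2 and the two rods during cyclic
flexion–extension (5°/s, 30–50 cycles). The statistic is:

* relative movement `dx_i = ||x_L2(t_i) - x_rod(t_i)||` on a synchronized
  time grid (we synchronize by linear interpolation onto the overlap grid
  at the coarser rate; the original alignment procedure is not described);
* the centered mean absolute movement
  `x_hat = (1/n) sum_i |dx_i - mean(dx)|`, i.e. the mean absolute
  deviation of the distance series — invariant to constant offsets and
  linear in scale;
* the ratio `R_lf = x_hat_loose / x_hat_fixed`, with the screw declared
  loose when the ratio **strictly** exceeds 2. A ratio of exactly 2 is
  therefore *not loose*; the boundary follows the strict "exceeds"
  reading.

The summation index in the defining formula does double duty as screw
index and time index; we resolve it as one `x_hat` per screw computed
over its time-indexed series. A zero `x_hat_fixed` makes the ratio
undefined and raises an error rather than returning infinity.

## The synthetic generator

No public recordings exist, so the simulator emulates the statistical
structure the detector relies on. It is a *stand-in*: its parameters are
not cadaver-validated, and results on synthetic data demonstrate pipeline
correctness, not clinical performance.

* **Transfer path.** Each specimen's bone–implant path is a set of six
  damped resonant modes (90–1500 Hz nominal, damping ratios 0.03–0.07)
  whose impulse response is a sum of exponentially damped sinusoids.
  Specimen individuality comes from seeded jitter: ±8% mode frequencies,
  a bone-quality damping factor in [0.8, 1.25], ±20% gains.
* **Loosening.** The loose condition (i) downshifts modes by 12% and
  scales damping by 0.7 (a looser, sharper-ringing interface), (ii) adds
  odd-harmonic "rattle" distortion (cubic waveshaping, gain 0.1) from
  intermittent screw–bone contact, and (iii) adds high-passed (800 Hz)
  broadband noise at 0.15 of the signal RMS. Together these reproduce the
  only stated empirical signature — loose spectrograms carry more
  high-frequency and more distributed energy — and (iii) is deliberately
  specimen-independent so the signature generalizes across specimens, as
  cross-specimen generalization of the detector requires. The `separation`
  parameter scales all three contrasts; at 0, fixed and loose are
  generated identically (same seeds, same draws), giving an exact null.
* **Acquisition.** 4 specimens × 2 screws × 2 conditions × 50 sweeps
  (sensor ≡ screw, matching one glued microphone per screw head), ±5%
  gain and 0–3 ms onset jitter per sweep to emulate lifting and replacing
  the shaker, and measurement noise at 30 dB SNR. All seeds derive from
  one master seed through a counter-based scheme, so datasets are
  bit-reproducible.
* **Trajectories.** L2 rides a 150 mm arc at 5°/s over a ±20° cycle; each
  rod sits 25 mm from the L2 reference point along its micro-motion axis
  and oscillates along that axis with amplitude 1 mm (× gain 3 when
  loose), plus 0.05 mm tracking noise. Because offset and motion are
  collinear, the implant–vertebra distance is offset + scalar motion, and
  the mean absolute deviation scales exactly linearly with amplitude: with
  the noise turned off the computed ratio recovers the loosening gain to
  machine precision, which the tests assert at 1e-6.

What the simulator does **not** model: anatomically realistic bone
geometry or finite-element acoustics, torque-controlled testing-machine
physics, sensor nonlinearity, or inter-session drift. Passing tests on
synthetic data therefore show that the feature extraction, training,
fold handling and statistics are correct — not that the classifier would
reach any particular accuracy on real cadaveric recordings.

## Numerical choices and degenerate inputs

* STFT framing uses reflection padding by half a window; an input shorter
  than the padding is extended by cycling reflection.
* The dB floor (1e-10 amplitude) keeps silence finite at −200 dB; a
  constant spectrogram collection has zero variance and normalization
  refuses it rather than dividing by zero.
* Mel filters are unit-peak triangles; with 256 filters, FFT length 2048
  and a 22.05 kHz analysis rate no filter is empty, and the constructor
  errors if a configuration produces an empty filter.
* Batch normalization uses eps 1e-5 and momentum 0.9 running statistics;
  inference uses the running estimates, so single-sample prediction is
  well defined.
* WAV quantization rounds to the nearest 24-bit step; round-trips are
  exact to `2^-23`. The reader accepts 16-bit PCM and 32-bit float for
  convenience and rejects multi-channel or truncated files.
* Probability 0.5 classifies as *fixed* (strict threshold), mirroring the
  strict loosening-ratio threshold.

## Problem sizes used in tests and the acceptance script

The bundled checks run the full default design (800 recordings) for
dataset conformance and spectral-contrast checks. For classifier-training
checks we use the study conditions at reduced computational width: the
first 10 sweeps per screw (160 recordings), a narrow SE-ResNet
(8/16/32/64 filters — the same depth, stem and SE structure), 3 epochs and
a learning rate of 1e-3 matched to the narrow width. These sizes are desk-
scale choices: the synthetic contrast is strong enough that the full-width
network adds nothing to the correctness argument while costing an order of
magnitude more time. With those conditions the pipeline reaches 100%
leave-one-specimen-out accuracy at full separation and exactly chance
(50%) at zero separation.

## Known limitations

* The 218-frame canonicalization is a reconstruction; the original
  resampling/truncation step is undocumented.
* The reference experiment's fold-1 specificity (87.76%) is not an
  integer percentage
  of a balanced 100-recording negative set, implying an unstated test-set
  composition; our synthetic folds are balanced 100/100 and we do not
  emulate that discrepancy.
* The reference experiment's per-screw displacement and ratio tables are
  mutually inconsistent (the quotient of the reported displacements of
  one screw is 4.22 against a reported ratio of 6.95), indicating the
  displacements were summarized by some other statistic. We implement the
  defined statistic literally and do not attempt to reproduce the ratio
  table from the displacement table.
* Training hyperparameters (stem choice, normalization placement, batch
  size) are faithful reconstructions where the original is silent; each
  is documented above and configurable.
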