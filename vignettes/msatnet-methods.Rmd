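---
title: "Model and methods: multi-scale adaptive transformer networks for motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatnet)
```

## The problem

A motor-imagery brain-computer interface decodes which movement a user is
imagining from short multi-channel EEG epochs. Imagined movement suppresses
the sensorimotor mu (8–13 Hz) and beta (18–26 Hz) rhythms over the
contralateral motor cortex — event-related desynchronization (ERD) — so the
class information lives in band-limited power changes at specific channels,
buried in 1/f background activity. Two things make the problem hard: the
discriminative features span several frequency bands and long temporal
ranges, and EEG differs so much between people that a classifier trained on
one subject transfers poorly to another.

`msatnet` implements a four-part architecture for this setting:

1. **Multi-scale feature extraction (MSFE).** Two parallel branches of
   one-dimensional temporal convolution act as learned frequency filters — a
   long kernel (default 64 samples) for low frequencies, a short one (16) for
   high frequencies. Each branch then applies a depthwise spatial convolution
   across all channels (learning per-filter spatial patterns and collapsing
   the channel axis), batch normalization, an ELU activation
   (`elu(x) = exp(x) - 1` for `x < 0`, `x` otherwise), average pooling and
   dropout. Branch outputs are fused by feature-axis concatenation and passed
   through a further convolution, pooling and dropout stage.
2. **Temporal decoder.** A modified temporal convolutional network: `n = 2`
   residual blocks, each with `m = 2` dilated causal convolutions (kernel
   `K = 4`, dilation `b^(j-1)` in block `j` with base `b = 2`), each
   convolution followed by batch-norm, ELU and dropout, plus a residual
   connection and a post-block ELU. Causality means output `t` depends only
   on inputs at times `<= t`. The receptive field is
   `r = 1 + m (K - 1) (b^n - 1) / (b - 1)`; at the defaults `r = 19` pooled
   time steps, which the package verifies against a finite-difference probe
   (`empirical_receptive_field()`).
3. **Multi-head self-attention.** The decoder output, viewed as a sequence of
   `N` steps with `d` features, passes through `H = 2` parallel scaled
   dot-product attention heads (`d_k = d_v = d / H`), concatenation, and an
   output projection. We use the standard `1/sqrt(d_k)` score scaling. No
   positional encoding is added: the causal decoder already supplies temporal
   structure.
4. **Subject adapter (SA).** For cross-subject transfer, a residual
   bottleneck `x + U ELU(D x + b_D) + b_U` (down-projection to `r_b = d/4`,
   up-projection back) is inserted after the attention block. The
   up-projection starts at zero, so the augmented network is exactly the
   pre-trained network at the start of fine-tuning, and only adapter
   parameters are ever fine-tuned.

A flatten + fully-connected + softmax head yields class probabilities.
Training uses cross-entropy, Adam (learning rate 0.0008), batch size 64, a
per-row max-norm constraint of 0.25 on the final dense layer applied after
every optimizer step, Glorot initialization, and early stopping on a
stratified validation split (a 20% split with patience 50 by default; the
split details are our choice — the reference recipe states only that early
stopping was used).

## Evaluation protocols

*Within-subject*: train on one session of one subject, test on another
session of the same subject (`train_within_subject()`,
`split_by_session()`). *Cross-subject* (`run_cross_subject()`): (1) split the
target subject's trials in half, class-stratified and seeded; (2) pretrain
the full model on all pooled source-subject trials; (3) insert the adapter
and fine-tune only its parameters on the target's fine-tuning half; (4)
evaluate on the held-out half. The protocol asserts that non-adapter
parameters are bit-identical across steps 3–4.

## The synthetic-data generator

Real recordings of this kind cannot ship with a package, so every test runs
on `generate_subject()` / `generate_cohort()` output. A trial is

* 1/f-shaped Gaussian noise (frequency-domain synthesis, RMS 10 µV times a
  per-subject noise scale) on every channel, plus
* amplitude-modulated mu (8 µV) and beta (4 µV) sinusoids with random phase
  and a slow random envelope, at the subject's mu/beta peak frequencies, with
* the rhythm amplitude multiplied by `(1 - erd_depth)` at the trial class's
  ERD channels (left hand→C4, right hand→C3, feet→Cz, tongue→C3+C4 — the
  contralateral convention), and
* per-channel gains.

Subject shift (`shift_scale`) disperses channel gains (log-normal, sd
`0.4·s`), mu/beta peaks (normal, sd `1.5·s` and `2·s` Hz, clipped to
[6, 14] / [15, 30] Hz) and noise scale (log-normal, sd `0.3·s`);
`shift_scale = 0` gives identical subjects. All generation is a pure function
of parameters and seed via per-trial counter-derived substreams, so results
do not depend on generation order.

The amplitudes were fixed once at values giving a realistic single-trial
band-power signal-to-noise ratio (mu-band power ≈ 3–4× the in-band noise
floor at full amplitude, strongly suppressed at `erd_depth = 0.8`); a ridge
classifier on log band-power features — the classical baseline — separates
the 4-class task well at depth 0.8 and sits at chance at depth 0, which the
test suite checks.

**What a green test does and does not establish.** The generator emulates the
spectral and spatial structure a motor-imagery decoder exploits; it contains
no eye/muscle artifacts, no trial-to-trial nonstationarity beyond the random
envelopes, no volume-conduction correlations between channels, and no ERS
rebound. Passing the capacity and transfer tests therefore establishes that
the implementation can learn and transfer the intended class structure — not
that it reproduces published accuracies on real competition data, which would
require the real recordings and GPU-scale training.

## Numerical and design choices

* **Pooling stride.** The printed layer table gives the average-pooling
  layers stride 1, which would barely downsample and contradicts the later
  claim that the attention unit receives small-dimensional features. We use
  stride = pool length (non-overlapping pooling, the EEGNet-family
  convention); `pool_stride = "one"` exposes the literal reading.
* **Second convolution placement.** The source is ambiguous about whether the
  second `(1,16)` convolution is per branch or after fusion; the default
  follows the fusion reading, `second_conv = "branch"` gives the other.
* **Parameter count.** With the defaults (depth multiplier 1, fusion
  reading), the MSFE block for 22-channel input has 10,336 trainable
  parameters. No reading of the printed layer table reproduces the published
  3.1×10⁴ exactly; the closest is depth multiplier 3 with the fusion reading
  (28,256, 8.9% below). The audit (`parameter_audit()`) reports per-layer
  counts that must sum exactly to the total.
* **Attention projections.** Per-head weights are stored as `H` separate
  `[d × d/H]` matrices applied to the full input — equivalent to one fused
  `[d × d]` map; the printed per-head score normalization is typographically
  garbled and we use the standard `1/sqrt(d_k)`.
* **Receptive-field probe.** For dilation bases > 2 the set of influential
  inputs has holes (e.g. lags {0, 1, 3, 4} for `K = 2`, dilations {1, 3});
  the closed form measures the window width, so the probe reports the width
  from the earliest influential input, which coincides with the count for
  base 2.
* **Batch-norm.** Momentum 0.99, epsilon 1e-3, statistics per feature over
  batch, channels and time. Frozen layers (during adapter fine-tuning) use
  running statistics and stop updating them.
* **Biases.** Convolutions followed by batch-norm carry no bias (it is
  redundant with the batch-norm shift); the dense head and standalone
  convolutions do.
* **Ties and degenerate inputs.** Argmax ties break toward the lower class
  index; zero-length windows, overlapping session splits, duplicate class
  ids, unknown channel names and double adapter insertion are validation
  errors.
* **"1,000 iterations"** in the reference recipe is read as 1,000 epochs
  (configurable); the fine-tuning schedule (same learning rate, 100 epochs,
  patience 20) is our choice, as the source does not state one.
* **Epoch window.** GDF epoching defaults to 0–4 s from cue onset (the
  imagination period; `T = 1000` at 250 Hz). Whether the preparation period
  should be included is not stated; the window is configurable.

## Implementation notes

No deep-learning framework is available in the target environment, so all
layers, backpropagation, Adam, the max-norm constraint and early stopping are
implemented in R, with the convolution, batch-norm and ELU inner loops in
C++ (Rcpp). An end-to-end finite-difference gradient check covering every
layer type is part of the test suite. GDF reading is likewise a minimal
self-contained implementation of the GDF 2.x container subset used by
BCI-competition-style recordings (float32 or int16 records, mode-1/3 event
tables), validated by write/read round-trips on synthetic fixtures; byte
compatibility with arbitrary real-world GDF files is not claimed.

## The scaled test world

The full-size configuration (22 channels, 1000 samples, 16 filters, 1000
epochs) is too expensive for a CPU test budget. The training-based tests
therefore run a scaled world chosen once during development: 3 channels
(C3, Cz, C4), 128 Hz, 2 s trials (T = 256), 8 temporal filters per branch,
kernels (32, 8), fusion width 8, pooling 8 then 4 (so the attention unit sees
N = 8 steps of d = 8 features), decoder and attention unchanged in structure,
learning rate 5e-3, batch 32, and a fixed 24-epoch budget — the cheapest
recipe that reached convergence on every pilot seed. Convergence matters:
the reference recipe trains to convergence (up to 1000 epochs with early
stopping), and comparing under-trained models inverts the ablation
orderings, since smaller variants converge faster. Validation-loss early
stopping is not used in the scaled runs because these models spend their
first 10–20 epochs on a chance-level plateau (the 0.25 max-norm keeps early
logits near uniform) that small-patience stopping mistakes for convergence;
early stopping itself is exercised on a dedicated small fixture. Trial
counts (200/class train, 100/class test), ERD depths, the 9-subject cohort,
shift scale 1.0 and every pass threshold follow the stated experimental
conditions unscaled.

## Known limitations

* The networks are CPU-sized research implementations; no GPU path, no model
  serialization (reports carry accuracies and audits, not weights).
* The GDF reader targets the BCI Competition IV layout; exotic GDF features
  (per-channel sampling rates, other sample types) are rejected with format
  errors rather than parsed.
* Published benchmark accuracies on the real competition datasets are out of
  scope; nothing in the test suite claims them.
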