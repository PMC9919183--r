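---
title: "Matched-filter CNNs for inter-patient ECG beat classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched-filter CNNs for inter-patient ECG beat classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfbeat)
```

## The problem

Automatic heartbeat classification on single-lead ambulatory ECG assigns each
annotated beat to one of the AAMI super-classes — N (normal and bundle-branch
or escape beats), SVEB (supraventricular ectopics), VEB (ventricular
ectopics), F (fusion) and Q (unknown/paced). The clinically honest evaluation
protocol is *inter-patient*: the 44 usable records of the standard arrhythmia
database are split into a 22-record development set (DS1) and a 22-record
held-out test set (DS2), so no subject contributes beats to both sides. This
is substantially harder than intra-patient or random splits because beat
morphology varies strongly between individuals, and the classes are extremely
imbalanced (roughly 89% of beats are normal).

`mfbeat` implements a deliberately tiny classifier for this problem, built on
the matched-filter (MF) view of one-dimensional convolutional networks. A
matched filter — correlation with a known template followed by sampling the
correlation maximum — is the optimal linear detector for a known waveform in
additive noise. A `Conv1D` kernel with stride 1 computes exactly that
correlation; a global-max-pooling layer is the MF sampling device; a
nonlinearity plays the role of the threshold. The network therefore *is* a
bank of matched filters whose templates are the kernel weights, and those
weights can be pre-assigned from data instead of learned.

## Model

Each beat is represented by

* a 64-sample window at 128 Hz (0.5 s) centered on the annotated R-peak, or
  its first difference (front-padded back to 64 samples), or both as two
  channels; and
* four causal, dimensionless RR-interval features: the pre- and post-RR
  intervals, each normalized by the trailing mean of the last 80 ("local")
  and 400 ("global") intervals.

The beat branch correlates the window with `NF` kernels of length `NK`
(stride 1, zero-padded to the input length, one bias per kernel), applies
per-channel batch normalization and `tanh`, and takes each channel's maximum
over time. The RR branch treats the 4 features as a 4×1 sequence and applies
dense maps of widths 32/16/8 with ReLU along the last axis, flattening to 32
values. Concatenation (`NF + 32` values) feeds a dense softmax over 3, 4 or 5
classes. With 3 classes and `NK = 32` the whole network has 1267 parameters;
882 of them are trainable when the correlator is frozen:

```{r}
count_params(mf_model_spec(3, nk = 32, conv_trainable = FALSE))
```

Templates are arithmetic means of the training beats' feature windows per
group — sub-class (the default and best-performing granularity), AAMI
super-class, or record-by-sub-class. When `NK` is shorter than the window,
the central `NK` samples are kept: template energy away from the R-peak is
nearly constant and carries little class information, so roughly 16 samples
can be discarded from each edge of a 64-sample template.

## Training protocol

Class-weighted categorical cross-entropy (weights `N_total / (n_classes *
N_c)` when enabled), Adam at 1e-3, mini-batches of 512, at most 500 epochs.
Training stops early after 20 epochs without validation-loss improvement and
restores the best weights; the learning rate halves after 10 stagnant epochs
down to 1e-5. DS1 is itself split by record id (below 200 → training, the
rest → validation) to keep model selection inter-patient too.

Published protocol details the source leaves open, fixed here once:

* **Early-stopping patience 20, plateau patience 10, factor 0.5, floor
  1e-5** — "early stopping" and "adaptive learning rate scheduling" are
  stated without constants; these are the common framework defaults.
* **Batch-normalization epsilon 1e-3, momentum 0.99, bias init zero, Glorot
  uniform dense/default-conv init** — framework-conventional values.
* **Derivative length**: differencing a 64-sample window yields 63 samples
  while the published architecture shows a 64-long input; the derivative is
  front-padded with one repeated edge value. Under this convention the
  padded-then-cropped template equals the unpadded derivative's samples
  [15, 47), matching the "about 16 from each edge" description; the choice
  is frozen by test.
* **Trailing RR means include the interval ending at the current beat**
  (inclusive window, averaged over whatever history exists during startup).
  The first and last beats of a record, whose pre- or post-RR interval does
  not exist, are dropped rather than imputed. Both conventions are recorded
  decisions; the source states only "calculated using past values".
* **Peak-index rounding on resampling** is round-half-to-even; resampling is
  zero-stuff / windowed-sinc FIR / decimate (360 → 128 Hz reduces to 16/45).
  Only the target rate is published; this is the standard anti-aliased
  choice.
* **Template amplitude normalization**: none. The source's timing table
  mentions a "normalization" step in template computation without defining
  it; templates here are plain means, and that choice is visible in the
  template-bank metadata.
* **Ties** in the MF argmax break lexicographically by label, for
  determinism.

## The synthetic world

Because the arrhythmia database cannot be redistributed, every test runs on
a seeded synthetic generator. It emulates exactly the properties downstream
code consumes:

* **Morphology**: each class is a sum of Gaussian deflections standing in
  for P/QRS/T waves. Defaults define three mutually distinguishable classes:
  `N` (P wave, narrow tall positive QRS, T wave; RR 0.80 s), `A` (early
  P fused toward the QRS, slightly wider QRS; RR 0.60 s — an atrial
  premature beat), and `V` (wide negative QRS, no P, large discordant T; RR
  0.55 s — a ventricular ectopic). Distinct QRS width/polarity per class is
  what makes matched filtering meaningful; the RR means give the causal RR
  features class information, as in real arrhythmias.
* **Annotation semantics**: the annotated index is the sample of maximum
  absolute QRS deflection, mirroring R-peak annotations.
* **RR dynamics**: the gap to the previous beat is the incoming beat's class
  mean plus Gaussian jitter (sd 0.04 s by default, a plausible short-term
  heart-rate variability scale).
* **Noise**: additive white Gaussian noise with variance equal to a stated
  percentage of the clean record's mean squared amplitude — the "noise power
  as a percentage of signal power" definition, applied globally because no
  windowing is published. The generator adds noise at its native rate
  (before downsampling); whether the published experiments did is unstated,
  so this is recorded as a choice, not an inference.
* **Mix**: class probabilities default to 0.8/0.1/0.1 — imbalanced enough to
  exercise class weighting, mild enough that a few hundred beats contain all
  classes.

What the generator does **not** emulate: baseline wander, electrode motion
artifacts, morphology drift within a subject, true inter-individual
variation (each synthetic "record" has one morphology per class), and the
long-tailed sub-class structure of real data. A green synthetic test
therefore establishes that the pipeline, features, architecture, training
and metrics are implemented correctly and that the method recovers known
structure in a favorable world — it does not establish clinical-grade
performance, which is exactly why the headline inter-patient numbers are a
separate acceptance criterion that requires the real database.

## Numerical choices and degenerate inputs

* The correlator layer and the free-standing `correlate()` primitive share
  one alignment convention (left pad `floor((K - 1) / 2)`); a test asserts
  channel-wise equality of the frozen conv branch with `correlate()` plus
  bias to 1e-5, making the MF interpretation executable.
* Backpropagation is hand-written; analytic gradients are checked against
  central differences to 1e-4 relative on every layer.
* Softmax subtracts the row maximum before exponentiation;
  cross-entropy clamps probabilities at 1e-12.
* Metrics with zero denominators (a class never predicted, or absent from
  the test set) are reported as 0 and flagged; zero-support classes are
  excluded from macro averages with a warning.
* Records shorter than one beat, empty signals, unsorted peaks, unknown
  record ids and mismatched template banks all fail fast with informative
  errors; unknown annotation symbols are skipped with a count, since real
  records contain rhythm and quality annotations.
* Scaled-down schedules: the noise-robustness acceptance test trains on
  ~1100 beats with batch 128 and at most 150 epochs so the whole suite fits
  a 1-CPU budget; the package defaults keep the published 512/500.

## Known limitations

* No R-peak detector: beats come from annotations, as in the published
  protocol; deployment would need a peak detector and a denoising
  front-end, both out of scope.
* Training is single-threaded R; the full real-data experiment (51k beats,
  ten seeds) takes tens of minutes per seed on one CPU.
* WFDB support covers single-annotator, uniform-format records in formats
  212/16/80 — sufficient for the arrhythmia, INCART, QT and PTB databases'
  common layout, not a general WFDB implementation.
* Exact bit-reproducibility is promised only within one numerical
  environment; across BLAS builds, results may differ in the last digits.
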