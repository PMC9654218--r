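---
title: "Multi-kernel temporal and spatial convolution for EEG emotion classification: models and methods"
author: "multits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-kernel temporal and spatial convolution for EEG emotion classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multits)
```

## The problem and the model

Scalp EEG for affective computing arrives as multi-channel voltage time
series (microvolts) segmented into short windows — 2 s here — each carrying
one discrete emotion label and a subject identifier.  Class-relevant
structure lives at several time scales at once: slow theta/alpha rhythms
(4–12 Hz), faster beta activity, and gamma (>32 Hz) whose hemispheric
asymmetry tracks emotional valence.  A convolutional classifier with a
single temporal kernel length must trade coverage of slow waves against
resolution for fast ones.

The MultiT-S ConvNet resolves the trade by *factoring the temporal stage
into four parallel kernels* with durations 25, 50, 100 and 200 ms.  Kernels
are stored as durations, not sample counts, so the same receptive time
scales carry across datasets with different sampling rates; at 200 Hz they
become 5/10/20/40 samples.  Each branch applies a zero-padded ("same")
convolution, ReLU, and a shared average pooling; branch outputs are
concatenated into `Fte = 24 x 4 = 96` temporal feature maps.  The longest
kernel fixes the lowest frequency completing a full cycle inside a filter:
`fs / 40 = 5 Hz` at 200 Hz (`minFrequencyCovered()`).

Spatial structure is learned by a depthwise-separable convolution: for each
temporal map, `featureMultiplier = 2` spatial filters spanning all `E`
electrodes (no padding, so the electrode axis collapses to 1), followed by
a pointwise (1×1) mix down to `Fsp = 64` temporal–spatial maps.  Both the
temporal and the spatial stacks are recalibrated by squeeze-and-excitation
(SE) gates: global average pooling to one descriptor per map, a bottleneck
of width `max(1, floor(F/r))` with `r = 16` and ReLU, then sigmoid gates in
(0, 1) that rescale each map.  The head is a single affine map: one sigmoid
unit with binary cross-entropy for two classes, three softmax units with
categorical cross-entropy for three.

The comparison families — Deep ConvNet, Shallow ConvNet and EEGNet — are
built from the same layer vocabulary, and `multikernelify()` applies the
reform studied in the ablation: the temporal convolution is replaced by the
four-branch block with per-branch filters equal to half the original
temporal filter count, every downstream filter count is halved, and a
batch-norm stage follows the concatenation.

## Reconstructing the published configurations

The source tables print seven trainable-parameter totals but not the full
layer settings, so the package fixes its canonical configurations by
solving the totals exactly.  One consistent convention set reproduces all
seven: a 62-channel input (the public montage size; the stated 64 is not
attainable for the Shallow total, whose spatial convolution alone would
overshoot), a 1-unit binary head, biases on every convolution, batch-norm
(two affine parameters per feature) after each convolution stage, and SE
dense layers without biases.  Within that convention the remaining free
lengths are pinned by the totals: Deep ConvNet uses 6-sample kernels with
valid padding and max-pool 3; Shallow uses a 10-sample kernel with average
pooling of length 50 and stride 10; EEGNet uses the classical `fs/2`
temporal kernel, 16-sample separable kernel and pools 4/8; its reform
halves the pointwise width to 32 and extends the second pool to length 14.
Two printed values cannot be reconciled and are *not* reproduced: the
"minimum frequency covered" entries of 40 Hz (Deep) and 17 Hz (Shallow)
conflict with the kernel lengths required by the parameter totals (6 and 10
samples give 33.3 Hz and 20 Hz); `minFrequencyCovered()` always computes
`fs / longest kernel` from the spec rather than echoing a table.

```{r counts}
countParamsClosedForm(multitsSpec())
countTrainableParams(buildModel(multikernelify(eegnetSpec())))
```

Every count is available through two independent routes — the closed-form
per-stage arithmetic from the spec and the element count of the actually
instantiated weight arrays — and the test suite requires exact agreement on
randomized specs, not only the canonical ones.

## Training engine and numerical choices

No neural-network framework is assumed: the package carries its own
feed-forward engine.  Tensors are laid out `(features, time, space, batch)`
so per-feature broadcasting is native in R and every convolution reduces to
one BLAS matrix product via im2col.  Backpropagation is hand-derived per
layer and verified against central finite differences to 1e-6 in the test
suite.  Optimisation is Adam (step size 1e-3, moments 0.9/0.999, epsilon
1e-8) — the step size is a recorded default, the original work not stating
one — with minibatches of 100 and the best-validation-accuracy checkpoint
retained (a "final epoch" alternative is selectable).  Weight
initialisation is Glorot-uniform from the spec's recorded seed; batch-norm
uses batch statistics in training and running averages (momentum 0.1) at
evaluation; dropout (EEGNet family, rate 0.25) is active only in training.
Degenerate constructions fail fast: pooling that exhausts the time axis
names the offending stage, and classifier heads other than 2 or 3 classes
are refused.

Inputs are standardised per channel with training-fold statistics before
training — a leakage-safe choice the package makes explicit because raw
microvolt scales otherwise put sigmoid heads deep into saturation.

## Spectral features and baselines

The classical baseline path estimates the power spectral density by Welch's
method: Hann-tapered segments of 1 s with 50% overlap (both configurable),
density-scaled so the one-sided spectrum integrates to the signal variance,
averaged per channel.  Band powers integrate the density over half-open
bands `[lo, hi)` — theta 4–7, alpha 8–12, beta 13–32, gamma 32–45 Hz (the
open-ended gamma band is capped at 45 Hz, matching the common 4–45 Hz
emotion-EEG bandpass, or at Nyquist if lower).  Integration is a Riemann
sum over the selected bins: every bin carries full weight, so a spectral
peak contributes the same total whether it sits mid-band or adjacent to a
band edge (a trapezoid would half-weight the edge bin and clip
edge-adjacent peaks by ~8%).  Features are flattened channel-major into
`channels x 4` columns; a raw-power default with an optional log10 switch
reflects that the baseline normalisation was left open in the source.

The baselines themselves are fixed-hyperparameter classifiers: KNN with 21
neighbours (Euclidean distance; ties broken deterministically toward the
smallest label index; k clamped with a warning when the training fold is
smaller), random forest with 100 trees, and a fully connected network with
two hidden layers of 100 logistic-sigmoid units trained with Adam.  The
FCN's output layer is zero-initialised, so an untrained network predicts a
single class and scores exactly the class prior.

## Cross-validation and statistics

Subject-dependent evaluation uses 5-fold cross-validation, stratified by
subject and class (switchable): per fold 20% of epochs are test, and a
random 30% of the remaining pool — stratified across subjects with
largest-remainder top-up so the total is exact — is validation.
Subject-independent evaluation is leave-one-subject-out: the held-out
subject is the test set and 30% of the remaining epochs, deliberately not
balanced across subjects, are validation.  Accuracies aggregate
subject-first: the mean, sd and a 95% Student-t interval are computed over
per-subject means.  The chance level is the majority-class rate.

Model comparison follows the flat one-way design: fixed-effects ANOVA over
per-model accuracy vectors, then Dunnett's two-sided many-to-one
comparison of every model against the proposed one, with adjusted p values
from the joint multivariate-t distribution of the contrast statistics
(correlation `sqrt(ni nj / ((ni+n0)(nj+n0)))`, pooled error term),
evaluated by mvtnorm's seeded quadrature.  Accuracies are analysed on the
raw proportion scale.  Paired t-tests serve the ablation contrasts.  The
test suite calibrates the procedure: under a simulated 7-group null the
family-wise error rate over 10,000 replicates must sit inside the 99%
binomial interval around 0.05.

## What the synthetic generator emulates — and what it does not

Access-restricted benchmark recordings are out of scope, so the package
ships a generator whose defaults mirror a SEED-like study: 15 subjects, 62
channels at 200 Hz, 2 s epochs, three emotion classes.  Each epoch sums,
over the four bands, a sinusoid with class-dependent amplitude, uniformly
jittered centre frequency within the band and uniform random phase, scaled
by a smooth per-band spatial topography (alpha and gamma carry opposite
left/right asymmetries, echoing the valence-lateralisation literature),
multiplied by a per-subject band multiplier (relative sd 0.2 — the
across-subject distribution shift), on top of per-channel 1/f background
noise of 10 µV RMS.  Default class amplitudes separate classes mainly in
alpha (10/8/6 µV for negative/neutral/positive) and weakly in gamma —
oscillations at or below the noise RMS, a realistic signal-to-background
regime.  Generation is a pure function of the configuration, seed
included.

This emulates band-limited class structure, topography, subject shift and
coloured noise; it does not emulate artifacts (ocular, muscular), volume
conduction between channels (channels share a deterministic topography,
not a mixing matrix), non-stationarity within an epoch, or label noise.
Passing the synthetic criteria therefore demonstrates that the
architecture, training loop and harness work end to end and that the model
can exploit band-limited contrasts — it does not certify accuracy levels
on real recordings.

## Problem sizes of the shipped property checks

The performance properties run at desk scale, chosen once: the
learnability check uses the alpha-contrast condition (9 vs 4 µV alpha over
6 µV noise) with 4 subjects and 50 epochs per class per subject (200 per
class in total), 4 channels at 100 Hz, a reduced MultiT-S instantiation (4
filters per branch, Fsp 8, SE ratio 4), 30 training epochs, and the median
over 5 seeds of single held-out-fold accuracy, required to exceed chance
by 0.15.  The multi-scale check splits the class signal between ~5 Hz and
~35 Hz components (two subjects, 30 epochs per class each) and requires
the four-branch model's median to be at least the single-25 ms-branch
model's.  The SE ablation repeats the alpha condition (two subjects, 25
epochs per class each) and requires that removing both SE blocks does not
improve the median.  The null pipeline check uses identical class
amplitudes (160 epochs) and requires every model — the three baselines and
the reduced MultiT-S — to stay within three binomial standard deviations
of the chance level under full 5-fold cross-validation.

## Known limitations

* The engine is CPU-only and R-level; it is sized for the shipped
  synthetic studies, not for full-scale benchmark training.
* The canonical configurations are reconstructions: they reproduce all
  seven published parameter totals exactly under one convention set, but
  layer details the totals do not constrain (activation placement inside
  the separable stage, dropout rates) follow the comparison families'
  original descriptions and are configurable rather than certain.
* EDF import covers the plain continuous-recording dialect with a single
  sampling rate across channels; BDF/GDF and mixed-rate files are refused.
* The Shallow ConvNet's published 17 Hz coverage figure and the stated
  64-channel montage are knowingly not reproduced (see above); both
  channel counts remain supported by configuration.
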