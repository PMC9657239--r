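---
title: "Few-shot recognition in the frequency domain: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot recognition in the frequency domain: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Plant-disease image collections are chronically short of labeled examples:
new diseases, new crops and new imaging conditions appear faster than
curated datasets. Few-shot learning (FSL) addresses this by evaluating a
model on *episodes*: an N-way/K-shot task draws N classes never seen in
training, gives the model K labeled support images per class, and asks it
to classify N·W further query images. `freqshot` implements a metric-based
FSL pipeline that operates on a JPEG-style *frequency representation* of
the image rather than on raw pixels, plus a *Gaussian-like calibration* of
feature vectors before distance measurement. Both components are modular
and can be used independently.

## The frequency frontend

An RGB image is resized (shorter side to
`floor(filter_size * image_size * 1.15)`, aspect preserved) and
centre-cropped to a square of side `filter_size * image_size`, converted to
YCbCr, chroma-subsampled 4:2:0 (Cb and Cr at half resolution), and each
plane is cut into `filter_size × filter_size` patches. Every patch `X` is
transformed with the orthonormal type-II DCT matrix `C`:

    Z = C X Cᵀ,   C[0, j] = 1/√S,   C[i, j] = √(2/S) · cos((2j+1) i π / 2S)

Coefficients with the same frequency are collected across patches into
*sub-channels*, numbered by the JPEG zigzag order (0 = DC). An `S × S`
filter yields `S²` sub-channels per plane, `3S²` in total (48, 192, 768 for
S = 4, 8, 16), each of spatial side `image_size`. Chroma sub-channels are
upsampled back to luma resolution, the retained channels are concatenated,
and each retained channel is standardized with mean/sd statistics computed
once over the training split.

Channel retention is either rule-based — the full set; the low-frequency
triangle `i + j ≤ S−1` including the minor diagonal (108 channels at
S = 8); the triangle without the diagonal (84); or an explicit list — or
*learned*: a squeeze-and-excitation (SE) block in front of a small encoder
is trained jointly during an image-wise pre-training pass over the full
channel set, its per-channel sigmoid gates are averaged over every sample
of the final epoch, and the top-N channels by mean gate are kept.

Design choices the frontend had to make where the method description is
silent, all exposed as arguments:

* **YCbCr variant.** Full-range ITU-R BT.601 (JPEG convention): achromatic
  pixels map to `Cb = Cr = 128`, outputs clamped to `[0, 255]`.
* **4:2:0 operator.** 2×2 block averaging rather than decimation — the
  standard stable choice.
* **Chroma upsampling.** Nearest-neighbour by default, bilinear selectable.
* **Level shift.** No JPEG −128 shift before the DCT; the shift affects
  only the DC coefficient, and the per-channel normalization absorbs any
  constant offset anyway.
* **Divisibility.** Plane sizes not divisible by the filter are a hard
  error; `preprocess_image()` guarantees divisibility (its output side is a
  multiple of `2 * filter_size`), and nothing is ever padded silently.

## The episodic classifier

The encoder `f_θ` maps a representation to a d-dimensional embedding. The
centroid of episode class `i` is the mean of its K embedded support
samples. A query `q` is scored against the calibrated centroids by cosine
similarity, converted to class probabilities by a softmax over the raw
cosines — deliberately without a temperature, so the exponent is the cosine
itself — and trained/evaluated with mean cross-entropy over the N·W
queries. Probabilities below `1e-12` are clamped (with a warning) so a
degenerate episode cannot produce an infinite loss.

Two encoders are provided, interchangeable behind `encoder_spec()`:
`tiny_cnn` (three conv-ReLU stages, two max-pools, global average pooling;
default 64-d embedding), which runs the entire pipeline on one CPU core in
minutes and is the default everywhere, and `resnet12` (the common few-shot
variant: four residual blocks of widths 64/160/320/640, each followed by a
2×2 max-pool, 640-d embedding) for full-scale runs. Layers are implemented
directly on base-R arrays with im2col convolutions and hand-derived
reverse-mode gradients; the test suite pins every layer and the SE block to
finite-difference gradient checks. Pre-training is plain SGD (momentum 0.9,
per-epoch multiplicative learning-rate decay) on an image-wise
classification objective over the source classes, with the dense head
discarded afterwards. Optimizer settings are exposed as arguments since no
canonical values exist for this setup.

After a learned selection the encoder is rebuilt for the reduced channel
count and retrained from scratch — its first-layer shape changes, so
reusing weights is not possible; the selection-pass encoder is a throwaway.

The SE *selection pass* deserves a note: DCT sub-channels are oscillatory,
so the global-average-pool squeeze statistic is nearly zero for AC
channels and the gate ranking is driven largely by the learned bias path.
That signal accumulates more slowly than the classification loss falls, so
the selection pass defaults to 12 epochs (`selection_epochs`) — longer than
the 5-epoch encoder pre-training — before the final-epoch gates are
averaged. With fewer selection epochs the ranking is close to its 0.5
starting point and effectively arbitrary.

## The Gaussian-like calibrator

Embeddings of ReLU networks are typically right-skewed, and cosine-to-
centroid classification is sensitive to the mismatch between a skewed
training distribution and novel-class test distributions. The calibrator
re-expresses each vector through four steps, in configurable order:

1. **Vertical slide** — subtract the vector's own minimum if negative, so
   all values are non-negative. The shift is strictly per-vector; sliding
   by dataset-level statistics would leak information across samples and is
   not offered.
2. **Tukey power transform** — `(v + ε)^β` for `β > 0`, `log(v + ε)` at
   `β = 0`, `−((v + ε)^β)` for `β < 0` (the negation keeps the map strictly
   increasing). `ε = 1e-6`; `β` defaults to 0.5, the strongest setting in
   practice, with the grid `{1.5, 1, 0.5, 0, −0.5, −1}` supported.
3. **Euclidean normalization** — scale to unit L2 norm.
4. **Centralization** — subtract the mean, making values symmetric about
   zero. Idempotent.

The default order is slide → PT → normalize → centralize; a slide is
inserted automatically whenever PT is configured without one. The
alternative normalize-before-PT ordering is selectable. Calibration is
applied at evaluation time to both query embeddings and centroids; whether
it also belongs inside a meta-training loss is left to the caller, since
either reading of the method is defensible.

## The synthetic data

Real plant-disease benchmarks are large, external and GPU-scale; the
package instead ships generators that reproduce the *statistical structure*
the method assumes, at desk scale.

**Leaf images** (`synthetic_image_spec()`): each image is a soft-edged
elliptical "leaf" on a uniform board, carrying a class-specific sinusoidal
lesion texture — one hue and one spatial-frequency band per class, with
per-image random orientation, phase, geometry jitter and Gaussian pixel
noise. Two deliberate renderer choices keep the frequency behaviour
analytically predictable: the board color is matched to the mean leaf
color, and the leaf boundary is softened over ~2 px, because a hard
high-contrast outline spreads `1/f²` energy across every DCT band and
would drown the lesion signal that distinguishes the classes. Class
parameters are interleaved across the source/target split, so the splits
are disjoint in both class identity and parameter values. Defaults — 8
source classes, 5 target classes, 20 images per class, 64 px — are the
package's standing desk-scale study conditions. What these images do *not*
emulate: natural leaf venation and shape variety, multi-disease leaves,
field backgrounds, illumination changes. A test passing on them shows the
pipeline's mechanics and its frequency selectivity, not field performance.

**Feature clusters** (`synthetic_feature_spec()`): class `c`'s centroid is
`separation` times a unit basis direction (random unit directions when
there are more classes than dimensions), plus i.i.d. Gaussian or
log-normal noise. The log-normal option produces the right-skewed
marginals the calibrator targets. The calibration-benefit condition used
by the tests and the acceptance script — 8 classes, 64 dimensions,
log-normal(0, 1) noise, separation 3, 5-way 1-shot — places the task in
the regime where single noisy supports make episodes genuinely hard, which
is where calibration earns its keep; with very large separations the task
saturates and calibration has nothing left to correct.

## Problem sizes and numerical choices

The package's own evaluations default to 100 episodes per epoch and one
epoch, with 15 queries per class; a full-scale evaluation in this field
conventionally runs 600 episodes per epoch for 10 epochs, and both knobs
are plain arguments. The episodic sampler, augmentation, initialization
and training all consume the ordinary R random stream, so a single seed
reproduces an entire experiment; `run_config()` carries a hash of itself
into every result row.

Tolerances used in the oracle tests: DCT orthonormality to `1e-10`,
brute-force DCT equivalence and round-trips to `1e-8`, probability
simplex and softmax oracles to `1e-9`, calibrator norm/mean identities to
`1e-12`. Ties in top-N selection are broken deterministically (plane order
Y < Cb < Cr, then ascending zigzag index); ties in max-pooling route the
gradient to the first matching position.

## Known limitations

* The conv-net stack is single-threaded base R: ResNet12 at full
  resolution is functional but not fast; it exists for architectural
  fidelity and small-scale checks.
* SE gate aggregation (mean over final-epoch samples) is one reasonable
  protocol among several; gates from a separate frozen pass or an average
  over epochs would also be defensible.
* The spatial and frequency branches share one encoder family but are
  trained independently; `concat_spatial_frequency()` joins their
  embeddings, and any interaction between the two representations is left
  to the encoder consumer.
* Accuracies on the synthetic study are not comparable to published
  benchmark numbers on real plant-disease datasets; they measure the
  pipeline against its own synthetic conditions only.

## A worked sketch

```{r example}
library(freqshot)

cfg <- run_config(seed = 1)      # synthetic study, 2x2 grid
ex <- run_experiment(cfg)
tidy(ex)                         # one row per domain x calibration cell
autoplot(ex)

# the frontend alone
sel <- fixed_selection("upper_tri_incl_diag", S = 8)   # 108 channels
img <- load_image("leaf.png")
rep <- transform_image(img, sel, filter_size = 8, image_size = 32)

# the calibrator alone
v <- rlnorm(512)
sample_skewness(v)
sample_skewness(calibrate(v, calibrator_config(beta = 0.5)))
```
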