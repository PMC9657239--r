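# freqshot

Few-shot learning for plant-disease image recognition in the frequency
domain, for researchers in image-based plant phenotyping and few-shot
methods who need the full pipeline — JPEG-style block-DCT frontend,
attention-based frequency-channel selection, Gaussian-like feature
calibration, and episodic nearest-centroid evaluation — as composable,
tested R functions.

## The method

Labeled plant-disease images are scarce, so the classifier is evaluated on
**N-way/K-shot episodes**: N novel classes (disjoint from the training
classes), K support images per class, and W query images per class to
classify. The pipeline has four stages:

1. **Frequency frontend.** The RGB image is resized and centre-cropped to
   side `filter_size * image_size`, converted to full-range YCbCr, chroma
   is 4:2:0-subsampled, and each plane is cut into `S x S` patches
   transformed by the orthonormal type-II DCT, `Z = C X Cᵀ` with
   `C[i,j] = √(2/S)·cos((2j+1)iπ/2S)` (`1/√S` in row 0). Same-frequency
   coefficients form zigzag-numbered sub-channels — `3S²` in all (192 for
   the standard 8×8 filter).

2. **Channel selection.** Keep all channels, a low-frequency triangle (108
   or 84 channels at S = 8), an explicit published list, or the **top-N by
   learned squeeze-and-excitation gates** trained on the source split.

3. **Gaussian-like calibration (GC).** Each embedding `v` is slid
   non-negative, re-expressed by the Tukey power transform
   `(v + ε)^β` (log at β = 0, negated power for β < 0; ε = 1e-6, β = 0.5
   by default), L2-normalized and centred — aligning the typically
   right-skewed CNN feature distribution with a symmetric, Gaussian-like
   one.

4. **Episodic classification.** Class centroids are means of embedded
   supports, `C_i = (1/K) Σ f_θ(d(x_s))`; a query is assigned by a softmax
   over its raw cosine similarities to the calibrated centroids,
   `p(y = C_i | x_q) ∝ exp⟨g(f_θ(d(x_q))), g(C_i)⟩`, trained with mean
   cross-entropy.

Encoders (`tiny_cnn` for CPU-scale work, a ResNet12 variant for full-scale
runs) are implemented in base R with hand-derived gradients, verified by
finite-difference checks. Synthetic generators provide leaf-like images
whose classes differ in lesion hue and texture spatial frequency, and
skewed feature clusters for calibrator studies — so everything installs,
tests and runs without any external dataset.

## Worked example

Calibrating a right-skewed vector and measuring what it buys on hard
1-shot episodes over log-normal clusters:

```r
library(freqshot)

set.seed(7)
v <- rlnorm(512)
sample_skewness(v)                                    # 3.114
sample_skewness(calibrate(v, calibrator_config()))    # 1.462

df <- generate_feature_clusters(synthetic_feature_spec(
  n_classes = 8, dim = 64, per_class = 100, separation = 3,
  noise = "lognormal", seed = 1))
ev0 <- evaluate_episodes(df, n_way = 5, k_shot = 1, episodes = 200, seed = 2)
ev1 <- evaluate_episodes(df, n_way = 5, k_shot = 1, episodes = 200,
                         calibrator = calibrator_config(), seed = 2)
glance(ev0)$mean_accuracy   # 26.7  (% correct; chance is 20)
glance(ev1)$mean_accuracy   # 28.5  (calibration recovers ~2 points)
```

The skewness of the log-normal sample drops from 3.1 to 1.5 after
calibration, and 5-way 1-shot accuracy on the skewed clusters rises from
26.7% to 28.5% (chance 20%): the calibrator makes noisy single-support
episodes measurably easier for the cosine classifier.

The full study — synthetic leaf images, learned top-12 selection from the
48 channels of a 4×4 filter, encoder pre-training on 8 source classes,
5-way/5-shot episodes on 5 never-seen classes, with and without GC, in
both domains:

```r
ex <- run_experiment(run_config(seed = 1))
tidy(ex)[, c("domain", "gc", "accuracy", "n_channels")]
#>   domain  gc    accuracy n_channels
#> 1 spatial FALSE      100          3
#> 2 spatial TRUE       100          3
#> 3 freq    FALSE      100         12
#> 4 freq    TRUE       100         12
autoplot(ex)
```

On these synthetic conditions both domains saturate at 5 shots; the
frontend's value shows in that 12 learned frequency channels carry as much
class information as the full image.

A command-line wrapper over the same functions lives at
`inst/cli/freqshot.R` (subcommands `transform`, `select-channels`,
`calibrate`, `pretrain`, `episode-eval`, `simulate`, `run`).

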