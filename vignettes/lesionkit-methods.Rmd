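---
title: "lesionkit: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lesionkit: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lesionkit` is a desk-scale implementation of a hybrid dermoscopic-lesion
analysis pipeline: preprocessing, selective-kernel U-Net segmentation,
handcrafted feature extraction, metaheuristic feature selection, and a
hybrid convolutional-recurrent classifier. This vignette records the
models, the tunable parameters with their defaults and units, the
numerical choices, and what a passing test suite does and does not
establish. It states no empirical result that the tests or the worked
examples do not themselves compute.

## 1. Preprocessing

**CLAHE.** The image is divided into square tiles (`tile_size`, pixels,
default 8). Each tile's histogram over `levels` gray levels (default 256)
is clipped at

$$\beta = \frac{R}{g}\Bigl(1 + \frac{\phi}{100}\,(s_{max}-1)\Bigr),$$

with $R$ the tile pixel count, $g$ the level count, $s_{max}=g-1$, and
$\phi \in [0,100]$ the clip factor (default 2). The printed source formula
for the clip limit is typographically garbled; this standard form was
adopted because it reduces to the uniform bin height at $\phi=0$ (no
enhancement) and to no clipping at $\phi=100$, matching the text's
description of a clip factor "between 0 and 100". Clipped excess is
redistributed uniformly and iteratively until the residual is negligible
($<10^{-6}$ counts), so $\phi=0$ flattens the histogram *exactly* — a
property the tests rely on. Per-tile cumulative mappings are interpolated
bilinearly between tile centers. Color images are enhanced on the HSV
value channel only, leaving hue and saturation untouched (avoids hue
distortion; the source is silent on color handling).

**Wiener filter.** The classical adaptive local (Lee) form: per-pixel mean
$\mu$ and variance $\sigma^2$ over a `window`×`window` neighborhood
(odd, default 3; reflective padding), output
$Q = \mu + \frac{\max(0,\sigma^2-\nu^2)}{\sigma^2}(P-\mu)$. The noise
variance $\nu^2$ is estimated as the mean of the local variances when not
supplied — the standard estimator consistent with the source's "based on
the accuracy of the image noise variance estimation". Pixels with
$\sigma^2 = 0$ return the local mean (gain defined as 0, avoiding 0/0).
The gain lies in $[0,1]$, so the output range never exceeds the input
range.

**Resize.** Bilinear, pixel-center convention, default 224×224 (the
conventional deep-learning input size); nearest-neighbor behind a flag.
The synthetic pipeline keeps its native resolution (64×64 default) so the
tiny network and the images agree.

## 2. SK-UNet segmentation

The encoder has `stages` spatial resolutions (full configuration 6; tiny
desk-scale default 4 with `base_channels = 16`, channels doubling per
stage). Each stage is a 1×1 → 3×3 → 1×1 convolution bottleneck with batch
normalization and ReLU, squeeze-and-excitation (SE) channel re-weighting
from the globally pooled descriptor (reduction ratio `se_reduction = 8`),
and a 1×1 projection shortcut added residually — the source is ambiguous
about whether SE-Res includes a residual addition; addition was adopted.
Downsampling mixes max-pooling at stages 1–2 with 1×1 stride-2
projections afterwards; where exactly the "two max-poolings and three
strided projections" of the 6-stage network fall is unspecified, so this
documented assignment (pool 1–2, stride 3–5) is fixed.

Each decoder stage upsamples by a stride-2 transposed convolution,
concatenates the matching encoder output (classical U-Net skip; the
source states only the final multi-resolution concatenation, so both are
implemented), convolves, and ends in a **selective-kernel module**: three
3×3 branches with dilations (1, 2, 3) — the source says "different
dilated convolutions" without rates — summed into an integrated map,
globally pooled, passed through a bottleneck (`sk_reduction = 8`) to three
per-channel logits, softmax-normalized into attention weights
$(p_m, q_m, r_m)$ with $p_m+q_m+r_m = 1$, and used to weight the branches.
The head upsamples all decoder outputs to input resolution, concatenates,
and applies 1×1 conv → BN → ReLU → 1×1 conv → per-pixel softmax.

Training minimizes pixel-wise cross-entropy (an optional soft-Dice term
sits behind `dice_loss`; the source never names its loss) with Adam.
Argmax ties at prediction time go to the background class. The whole
network is base-R matrix algebra over im2col matrices computed by two
small Rcpp kernels; every backward pass is checked against central finite
differences in the test suite, which is the load-bearing guarantee for a
hand-derived implementation.

**Why the segmentation trainer defaults to lr 1e-3.** The reference
training protocol (Adam lr 1e-4, batch 32, 30 epochs) describes
full-scale training on thousands of images; it is kept as the package's
classifier/config default. The desk-scale segmentation recovery
experiment (20 images, batch 4, 30 epochs) performs only 150 optimizer
steps, for which lr 1e-4 is undertrained by construction; the
segmentation trainer therefore defaults to lr 1e-3. This was fixed as
experiment design before the recovery experiments were run.

## 3. Features

Per lesion, 277 named values in a fixed order (color → texture → shape;
the source's "ordered by diagnostic relevance" is not operationalized, so
the presentation order is used and recorded):

* **Color (12):** mean and population SD of R, G, B, S, V over masked
  pixels; hue is circular (resultant-vector mean, circular SD
  $\sqrt{-2\log\bar R}/2\pi$ in hue units).
* **GLCM Haralick (6 per distance):** the masked intensity range is
  binned uniformly into `levels = 8` gray levels; pair counts at
  distance 1 and angles {0°, 45°, 90°, 135°} over pixel pairs *both*
  inside the mask, symmetrized, normalized, then contrast
  $\sum p(m,n)(m-n)^2$, dissimilarity $\sum p|m-n|$ (the printed formula
  lacks the absolute value and would vanish on symmetric matrices), ASM
  $\sum p^2$, homogeneity $\sum p/(1+(m-n)^2)$, energy $\sqrt{ASM}$ (the
  printed energy formula is identically 1 for a normalized matrix), and
  correlation in the standard normalized-covariance form (the printed
  form is garbled; degenerate marginals return 1). Descriptors are
  averaged over the four angles by default for rotation robustness
  (per-angle output behind a flag).
* **LBP (256):** 8-bit codes from the signs of (neighbor − center) over
  the 3×3 window, ties counting as 1, clockwise from the top-left
  neighbor (most significant bit); histogram normalized to sum 1. Only
  pixels whose full window lies inside the mask contribute. The source's
  rotation/scale-invariance claim does not hold for the raw 256-bin
  histogram and is not asserted. Block-wise histograms (block side `N`)
  are available; the block size is never stated, so the whole-region
  histogram is the default.
* **Shape (3):** on the largest 8-connected component, dispersity
  $\rho^2/\Lambda$, saturation $\Lambda/\rho$, roundness
  $4\pi\Lambda/\rho^2$, with $\Lambda$ the pixel count and $\rho$ a
  contour-following perimeter. Raw chain-code length (diagonals
  $\sqrt2$) overestimates smooth boundaries by ~5%, which would break the
  analytic disk limit; the Vossepoel–Smeulders corrected estimator
  $0.980\,N_{even} + 1.406\,N_{odd} - 0.091\,N_{corner}$ is used. For a
  disk the three descriptors converge to $4\pi$, $r/2$ and 1 (the tests
  check 5% at radius 32 and monotone convergence); for a square the
  estimator's asymptote is ~4% above the analytic $\pi/4$, so the square
  check uses side 320.

## 4. FOA feature selection

Candidate subsets are continuous positions in $[0,1]^p$ binarized at
`threshold = 0.5` — this reconciles the source's conflicting binary-vector
and continuous-update descriptions. An empty subset is repaired by
force-including the highest-valued feature. Fitness (minimized) is
$(1-\text{acc}) + \alpha\,|S|/p$ with `subset_penalty` $\alpha = 0.01$:
$\alpha = 0$ reproduces the pure maximum-accuracy objective, but the text
demands an accuracy/size balance, so a small default penalty is used.
Accuracy comes from a 3-nearest-neighbor classifier under stratified
3-fold cross-validation (cheap and deterministic; the source never names
the wrapper's inner model), or — inside the pipeline — from fitting on the
training split and scoring on the validation split, so test data never
drive selection.

The attack phase moves each member toward a uniformly drawn strictly
better member ("lemur"): $s' = s + a(\psi - \zeta s)$ with
$a \sim U(0,1)$ and $\zeta$ drawn from $\{1,2\}$ per coordinate (the
source says "random numbers between 1 and 2"; the integer draw matches
the source metaheuristic's intent). The chase phase perturbs by
$(1-2a)(u-l)/\iota$, shrinking with the iteration counter $\iota$. Both
phases clamp to bounds and accept greedily — the prose says "higher
objective value" but the formulas accept on *lower* fitness, and the
formulas are followed, consistent with the candidate-set definition.
Population size and iteration count are never stated; defaults R = 20,
T = 50. With T = 0 the selection provably equals the binarized best
initial member, and for small dimension the wrapper fitness is shared
with an exhaustive enumeration oracle, so FOA can be checked against the
true optimum.

## 5. Hybrid 1D-CNN–GRU classifier

Selected features form a single-channel 1D sequence (order recorded in
the model). Two convolution blocks (filters 32/64, kernel 3, "same"
padding, no pooling — the sequences are short) with batch normalization
and ReLU; a GRU (hidden 64) consumes the sequence and its final hidden
state feeds a dense softmax head. The gates follow the standard update /
reset / candidate equations; the new hidden state is a per-coordinate
convex combination of candidate and previous state, which the property
tests assert. The printed batch-normalization formula is unreadable; the
standard form consistent with its symbol glossary is used, with batch
statistics in training and running statistics at inference. Features are
z-scored with statistics from the training split only (leakage control).
Layer counts and widths are never stated in the source; the defaults are
documented choices. Multi-class AUC is macro one-vs-rest from predicted
probabilities (the source reports a single AUC without definition);
zero-support classes contribute 0 to macro averages with a warning.

## 6. The synthetic world

`make_lesion_image()` states a simplified dermoscopy world: a skin-toned
background (RGB ≈ 0.91/0.75/0.65) with a linear illumination gradient
(amplitude 0.08) and Gaussian sensor noise (SD 0.02); one elliptical
lesion per image (random orientation, eccentricity ≤ 0.35) whose polar
radius is modulated by Fourier harmonics k = 2–4 with class-dependent
amplitude; fill color from class hue/saturation/darkness plus a
spatially correlated texture field (Gaussian-smoothed noise, class
correlation length); optional dark hair-like arcs (off by default). The
three default classes differ in hue (0.07/0.02/0.58), darkness
(0.55/0.38/0.50), texture smoothing σ (3/1/2 px), boundary irregularity
(0.04/0.14/0.28) and radius (0.28/0.32/0.23 of the frame) — values chosen
once as a plausible caricature of pigmented-lesion variation, strongly
separable by design. `make_feature_table()` plants class-conditional
Gaussian informative columns at a stated separation (SD units), noisy
linear copies as redundant columns, and standard-normal noise columns,
returning the informative index set for recovery scoring.

What this world does **not** emulate: real pigment network textures,
multi-component or low-contrast lesions, vignetting, rulers and gel
artifacts, class imbalance at clinical rates. Consequently a green test
establishes that a stage *recovers planted structure at the stated
tolerance* — e.g. held-out Dice ≥ 0.8 for the tiny SK-UNet, ≥ 4/5
informative features in ≥ 8/10 seeds, pipeline macro F1 ≥ 0.7 — and
nothing about benchmark dermoscopy performance, which requires external
data and full-scale training and is explicitly out of scope.

The FOA recovery experiment uses tables with informative and pure-noise
columns only (no redundant copies): a selected redundant copy is
statistically equivalent to its parent, so counting it as a miss would
measure tie-breaking, not discrimination. Redundant-copy behavior is
exercised separately (correlation contract in the generator tests).

## 7. Numerical choices and degenerate inputs

* Seeds: one global seed fans out via `derive_seed(seed, stage)` (a
  hash-mix kept below $2^{31}$), so each stage is reproducible in
  isolation; generators save and restore the caller's RNG state.
* CLAHE: a tile whose histogram mass cannot be redistributed (constant
  tile, no clipping) maps by the identity ramp; outputs clamp to [0,1].
* GLCM quantization bins the *masked* range; a constant region occupies
  one diagonal cell. Haralick correlation returns 1 when a marginal is
  degenerate.
* Perimeter of a single-pixel component is defined as 1 (keeps
  $\rho > 0$).
* Argmax ties in mask prediction go to background; k-NN vote ties go to
  the nearest tied class.
* Pipeline masks that cannot support feature extraction (no pixel with a
  full 3×3 foreground window) fall back to the ground-truth mask, so an
  undertrained segmenter degrades the experiment instead of crashing it.
* Batch-norm inference uses running statistics (momentum 0.1); training
  uses batch statistics.
* Split sizes are `round(n·fraction)` per split with the remainder to
  training; stratification applies the rule within each class.

## 8. Known limitations

* Training is CPU-bound R + small Rcpp kernels: minutes, not seconds, for
  the recovery experiments; no GPU path.
* The SK-UNet supports square inputs divisible by $2^{stages-1}$.
* The raw LBP histogram is high-dimensional and sparse for small lesions;
  uniform-pattern variants are out of scope.
* FOA's inner k-NN wrapper measures subset quality cheaply; it is not the
  final classifier, and selections optimal for k-NN need not be optimal
  for the 1D-CNN–GRU.
* The run report stores index sets for a leakage audit, but preprocessing
  is parameter-free per image, so no preprocessing statistics exist to
  audit.
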