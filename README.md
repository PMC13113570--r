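# lesionkit

Dermoscopy — magnified, illuminated imaging of skin lesions — is the
standard screening tool for melanoma, but automated analysis of dermoscopic
images must cope with low contrast, sensor noise, irregular lesion
boundaries, and highly redundant feature representations. `lesionkit`
implements a complete hybrid analysis pipeline for this problem at desk
scale, fully exercisable on seeded synthetic data, for researchers who want
a tested, reproducible reference implementation of each stage:

1. **Preprocessing** — contrast-limited adaptive histogram equalization
   (CLAHE) with per-tile clip limit
   `β = (R/g)(1 + φ/100·(s_max−1))`, an adaptive local Wiener (Lee) filter
   `Q = μ + max(0, σ² − ν²)/σ² · (P − μ)`, and bilinear resizing
   (default 224×224).
2. **Segmentation** — a selective-kernel U-Net (SK-UNet): encoder of
   squeeze-and-excitation residual bottleneck stages (six spatial
   resolutions in the full configuration), decoder stages ending in a
   selective-kernel module that fuses three dilated-convolution branches
   with per-channel softmax attention weights `p_m + q_m + r_m = 1`.
   Implemented from scratch in R with Rcpp convolution kernels and manual
   backpropagation (verified by finite-difference tests).
3. **Features** — 12 color statistics (RGB + HSV means/SDs, circular hue),
   six Haralick descriptors of masked gray-level co-occurrence matrices
   (contrast, dissimilarity, ASM, homogeneity, energy, correlation), the
   256-bin local-binary-pattern histogram, and shape descriptors
   (dispersity ρ²/Λ, saturation Λ/ρ, roundness 4πΛ/ρ²): 277 named values
   per lesion.
4. **Feature selection** — the Fossa Optimization Algorithm (FOA), a
   population metaheuristic with an attack phase
   `s′ = s + a(ψ − ζs)` toward strictly better members and an
   iteration-shrinking chase phase `s′ = s + (1−2a)(u−l)/ι`, minimizing
   `(1 − accuracy) + α·|subset|/p` with a k-NN wrapper.
5. **Classification** — a hybrid 1D-CNN–GRU: two convolution blocks over
   the ordered feature sequence, a gated recurrent unit along the sequence
   axis, and a softmax head; Adam defaults lr 1e-4, batch 32, 30 epochs,
   70/15/15 stratified splits.

## Worked example

```r
library(lesionkit)

# one synthetic lesion with exact ground truth
it <- make_lesion_image(class_id = 2, synth_image_params(size = 64), seed = 7)
fv <- extract_features(it$image, it$mask)
round(fv[c("color_r_mean", "color_v_mean", "glcm_d1_contrast",
           "glcm_d1_homogeneity", "shape_roundness")], 3)
#>        color_r_mean        color_v_mean    glcm_d1_contrast
#>               0.390               0.390               1.352
#> glcm_d1_homogeneity     shape_roundness
#>               0.615               1.013
```

Class 2 is the dark, rough-textured lesion family: its mean red/value of
0.39 sits well below the skin background (~0.9), the GLCM contrast of 1.35
reflects the short texture correlation length, and roundness near 1 says
this particular draw was close to circular.

```r
# known-structure table: 5 informative, 15 noise columns
tb <- make_feature_table(n = 300, p = 20, k = 5, r = 0, separation = 2, seed = 3)
sel <- select_features(tb$table, tb$labels, foa_config(dimensions = 20, seed = 3))
sel$names
#> "f4"  "f8"  "f9"  "f10" "f11" "f12" "f16" "f19"
length(intersect(sel$selected, tb$informative))
#> 5         # all informative features recovered
```

The full pipeline (synthesis → preprocessing → SK-UNet training → feature
extraction → FOA → 1D-CNN–GRU → held-out evaluation) runs end to end with

```r
cfg <- default_config()
cfg$synthetic$n <- 60L; cfg$synthetic$size <- 64L
cfg$segmentation$train$epochs <- 15L
cfg$classifier$train$learning_rate <- 1e-3
report <- run_pipeline(cfg)
#> [lesionkit:segment] (seed=318279350) test dice 1.000
#> [lesionkit:select] (seed=234181963) 1 / 277 features
#> [lesionkit:evaluate] (seed=414001656) test accuracy 1.000 macro F1 1.000
```

On the easy synthetic world the stages saturate: the tiny SK-UNet reaches
Dice 1.000 on held-out lesions and the classifier macro F1 1.000 on the
test split — the classes are separable by design, so these numbers verify
recovery, not clinical performance.

A command-line surface wraps the same stages:

```sh
Rscript -e 'lesionkit::lesionkit_cli()' synth images --out data/ --n 30 --seed 1
Rscript -e 'lesionkit::lesionkit_cli()' features --images data/ --masks data/ --out features.csv
Rscript -e 'lesionkit::lesionkit_cli()' select --features features.csv --out selection.json
Rscript -e 'lesionkit::lesionkit_cli()' run --out report.json --seed 1
```

## Scope

`lesionkit` makes no claim about clinical dermoscopy benchmarks. The
synthetic generators state a simplified world (see the methods vignette in
`vignettes/lesionkit-methods.Rmd`); green tests establish that each stage
recovers what that world plants, at the stated tolerances.
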