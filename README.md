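# dermacaps

Dermoscopy skin-lesion analysis in R: active-contour segmentation and an
attention-guided capsule-network classifier, with a synthetic image
generator so the whole pipeline runs on one CPU with no external data.

Early discrimination of malignant from benign pigmented lesions leans on
border and color cues: malignant lesions tend to have irregular, lobed
borders and variegated pigmentation. This package implements that
workflow end to end for binary benign/malignant classification:

* **Synthetic dermoscopy generator** — lesions with analytic boundaries
  `r(θ) = r0(θ)(1 + Σ aᵢ sin(fᵢθ + φᵢ))`, skin-toned background, hair
  strokes and bubbles, plus exact ground-truth masks. Benign lesions are
  near-elliptical (all `aᵢ ≤ 0.05`); malignant ones carry a strong
  harmonic (`aᵢ ≥ 0.25`) so their border irregularity index
  `P²/(4πA)` exceeds the clinical 1.8 threshold by construction.
* **Preprocessing** — bilinear resize (reference side 299), the
  mean–variance intensity normalization
  `K = N0 ± sqrt(VAR0·(H − N̄)² / VAR)` (population mean/variance hit
  `N0`/`VAR0` exactly; defaults 0/1), augmentation (rotation ±15°,
  flips, contrast 0.7–1.3, crop, noise), stratified 70/15/15 splits,
  PSNR/SSIM/MSE quality reports and class-assessment metrics
  (imbalance ratio, intra/inter-class distances, silhouette).
* **Segmentation** — a parametric snake `b·Y_vv − a·Y_vvvv + M = 0`
  evolved semi-implicitly in a diffused edge force field
  (`M_s = t(|∇g|)∇²M − B(|∇g|)(M − ∇g)`, `t = e^{−|∇g|/A}`,
  `g = |∇(G_σ * I)|`), with Otsu-based region pressure, morphological
  hair detection + inpainting, and even-odd rasterization to a binary
  mask.
* **Descriptors** — convexity, circularity `4πA/P²`, irregularity index
  `P²/(4πA)` with the 1.8 irregular/regular decision, local-sd texture
  maps, circular-hue color statistics.
* **Classifier** — residual bottleneck backbone (full 49-convolution /
  2048-d preset and a <100k-parameter `tiny` preset), CBAM
  channel/spatial attention `F' = Ms(Mc(F)⊗F)⊗F`, and a matrix-capsule
  head: 2 layers × 32 capsules of 4×4 pose, inverted dot-product
  attention routing (`M_ji = Z_ji N_j`, softmax of pose agreements over
  parents, layer-normalized parents), two class capsules of size 16 and
  a shared linear classifier. Trained with minibatch SGD (momentum 0.9,
  step 0.01) on a package-internal autodiff tape whose gradients are
  verified numerically in the tests.

## Worked example

```r
library(dermacaps)

dir <- file.path(tempdir(), "demo")
man <- generate_dataset(20, imbalance_ratio = 1, dir = dir, seed = 42)
attr(man, "class_counts")
#>    benign malignant
#>        10        10

img <- png::readPNG(man$image[11])   # a malignant lesion
gt  <- png::readPNG(man$mask[11])
seg <- segment_lesion(img)           # hair removal + force field + snake
dice_overlap(seg$mask, gt > 0.5)
#> [1] 0.958

sd_ <- shape_descriptors(seg$mask)
#> area 1495 px  perimeter 185.7 px  convexity 0.785  circularity 0.545
#> irregularity index 1.84 -> irregular (malignant-like border)

model_summary(build_capsnet(backbone_config("resnet50")))
#> conv layers: 49   feature dim: 2048
#> conv capsules: 64 (2 x 32 of 4x4)   class capsule size: 16
```

The segmented border of this star-shaped lesion overlaps the analytic
ground truth at Dice 0.958, and its irregularity index 1.84 sits above
the 1.8 decision threshold, flagging the border as irregular. The
summary confirms the reference architecture: 49 main-path convolutions
feeding a 2048-dimensional feature vector, 64 convolutional matrix
capsules and class capsules of size 16.

End-to-end training at desk scale:

```r
man <- generate_dataset(200, 1, dir = file.path(tempdir(), "train"), seed = 11)
res <- train_pipeline(man, sgd = sgd_config(epochs = 30, seed = 5), verbose = TRUE)
res$test_metrics   # accuracy / sensitivity / specificity / F1 / AUC on the held-out 15%
```

A command-line front end wrapping these functions ships in
`inst/cli/dermacaps.R` (subcommands `simulate`, `preprocess`, `segment`,
`features`, `model-summary`, `train`, `evaluate`).

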