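---
title: "Methods: the dermocad melanoma CAD pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dermocad melanoma CAD pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`dermocad` implements the stages of a computer-aided diagnosis (CAD) pipeline
for dermoscopic skin-lesion images: artifact removal, contrast restoration,
lesion segmentation, and binary melanoma (MEL) versus benign (BEN)
classification, together with the dataset preparation and evaluation
machinery such a pipeline needs. The package is built to be fully testable at
desk scale: a seeded synthetic image generator supplies dermoscopic-like
scenes with pixel-exact ground truth for every stage, so no external dataset
or GPU is required to exercise and verify the code.

The two-arm experiment at the top of the package contrasts a classifier
trained on raw images with the same classifier trained on images that first
pass through hair removal, contrast restoration, segmentation and a
region-of-interest (ROI) crop.

# Hairline removal

Dark curvilinear hairs are detected by grayscale morphology. With `I` the
grayscale image (luma weights 0.299/0.587/0.114) and `SE` a structuring
element, the pipeline computes

* closing: `(I ⊕ SE) ⊖ SE` — dilation then erosion; extensive and idempotent,
  it fills dark structures thinner than the element;
* the residue `Close(I) − I`, which is nonnegative and large exactly on thin
  dark structures;
* a binarization at `T = 25` intensity units (8-bit scale);
* a binary dilation that repairs mask boundaries and bridges gaps;
* repainting of masked pixels from their neighbours.

Design choices where the procedure leaves freedom:

* **Structuring elements.** Hairs are thin and of unknown orientation, so the
  closing uses a bank of line elements of length 15 at 0/45/90/135 degrees,
  combined by the per-pixel maximum of the four closings (a DullRazor-style
  choice). A single orientation misses perpendicular hairs.
* **Mask dilation.** A disc of radius 2. The dilated mask deliberately
  over-covers the hair so that the inpainting step only draws on clean donor
  pixels. Because a 1–3 px hair dilated by 2 px is several times wider than
  the ground-truth stroke, detection *quality* (the Dice score against
  ground-truth hair masks) is scored on the pre-dilation detection mask;
  the pixel-identity contract (pixels outside the mask are returned
  bit-exactly) is asserted on the dilated mask that is actually inpainted.
  `remove_hairlines()` returns both.
* **Inpainting.** Each masked pixel receives, per channel, the
  inverse-distance-weighted average of its 8 nearest unmasked pixels. This is
  deterministic and order-independent; it is a smoothness prior, not an
  exemplar-based texture fill, and will blur texture inside wide masks.
* Only dark-on-light hairs are detected (closing is one-sided); light hairs
  on dark skin are out of scope.

# Contrast restoration (MCAN)

Hair occlusion and repainting flatten local contrast. The multiscale context
aggregation network restores it. The network is built from eight context
modules (multiscale residual aggregation blocks, MRABs); each holds a 3×3
convolution with 32 filters at a fixed dilation rate — 2, 4, 6, 8, 16, 32,
64, 128 across the eight blocks — followed by batch normalization and a
leaky-ReLU. An adaptive-normalization pair of learnable scalars combines the
identity and normalized branches:

```
out = mu * x + lambda * BN(conv(x))
```

with `mu = 1`, `lambda = 0` at initialization, so an untrained stack is the
identity and gradients flow from the first step. A 3×3 entry convolution
lifts the RGB input to 32 channels (the first block's identity branch would
otherwise not match), and a 1×1 regression convolution maps back to 3
channels. Images are processed as 256×256 patches by default; patch
extraction pads by edge replication and stitching inverts it exactly.

Training minimizes mean squared error on (degraded, clean) pairs
manufactured from clean images by monotone gamma/gain intensity remaps —
the regression head makes MSE the natural loss. The training sampler draws
`gamma` from [1, 2] and `gain` from [0.85, 1]: including `gamma = 1` (the
identity) teaches the network to leave already-clean inputs approximately
unchanged, while the evaluation degradations use the harsher `gamma` in
[1.5, 2]. The network therefore learns an average inverse remap conditioned
on image content; it is not trained on real hair-occlusion artifacts.

# Lesion segmentation (ACNN)

The segmentation network uses atrous (dilated) convolutions: the kernel taps
of a rate-`r` convolution are spaced `r` pixels apart,

```
out(x, y) = sum_{i,j,k} I(x + i*r, y + j*r, k) * K(i, j, k),
```

which enlarges the receptive field without pooling or extra parameters
(rate 1 is the standard convolution). The implementation lowers the input
with a dilated im2col (C++) and multiplies by the kernel matrix; the test
suite verifies it against a direct triple-loop summation and against the
zero-inflated-kernel identity.

The architecture has 16 feature-extraction layers in 5 blocks
(3/3/3/3/4 layers), each conv → batch norm → leaky ReLU (slope 0.3
network-wide), with the dilation rate doubling per block (1, 2, 4, 8, 16) —
no pooling, stride 1 throughout, so the output resolution equals the input
resolution. A 1×1 convolution head and per-pixel softmax yield the
lesion/background maps. Per-block channel widths default to 16/32/48/64/64;
they are a free parameter chosen for desk-scale trainability. Training uses
weighted cross-entropy with inverse pixel-frequency class weights (a 90/10
background/lesion set gives the lesion a 9× weight) under SGDM with the
defaults batch 16, learning rate 0.01, L2 0.005, momentum 0.9, 30 epochs.

# Classification (N-DCNN)

The classifier is a compact 11-block CNN: a first convolution block with 8
kernels of 3×3 on a 128×128×3 input, three groups of conv blocks repeated
2, 4 and 2 times, a fully connected block and the softmax output block.
Every conv block is conv → batch norm → leaky ReLU (`s = 0.3`,
`leakyReLU(x) = s*x` for `x < 0`, `x` otherwise); a 2×2 max-pool follows the
first block and each group.

**Channel schedule.** The published design constraints are ~3.3 M learnable
parameters *and* ~3.1 K kernels over these blocks. A monotone channel
pyramid cannot satisfy both: 3,100 filters of 3×3 in 9 conv layers force
roughly 9·Σ(Cin·Cout) ≈ 10 M parameters. The default schedule is therefore a
squeeze/expand (bottleneck) alternation — `8 | 32,32 | 960,32,960,32 |
960,64` with a 320-unit fully connected layer — giving 3,268,018 parameters
and 3,080 kernels, inside both budgets. The budget is enforced at build time
for the default spec; reduced configurations opt out.

Training: SGDM (`v' = γv − α∇L`, `θ' = θ + v'` — classical momentum) with
learning rate 0.001, momentum 0.99, batch 32, L2 0.0005, weighted
cross-entropy `−(1/N) Σ_i Σ_j w_j T_ij log P_ij` with inverse class-frequency
weights. L2 decay is applied to weight matrices only (not biases or
normalization scales). MEL is the positive class everywhere, including the
reported AUC.

# Dataset operations

* **Deduplication**: grayscale Pearson correlation over flattened
  intensities (images resized to a common 256×256 raster when sizes differ);
  pairs above 0.99 within the same class are grouped by transitive closure
  and the first path in index order represents each group.
* **Splitting**: stratified 70/10/20 with largest-remainder apportionment,
  which reproduces class totals 5,789 → (4052, 579, 1158) and 7,093 →
  (4965, 709, 1419) exactly.
* **Oversampling**: the training split's minority class is resampled with
  replacement up to the majority count (4052 MEL vs 4965 BEN → 9,930 rows);
  validation and test sets are never touched, enforced structurally.
* **Augmentation**: seeded rotation in ±30°, 0.8 horizontal scale, ±5 px
  vertical translation, implemented as an inverse-mapped bilinear warp with
  reflect padding so the identity configuration is bit-exact and integer
  shifts are exact.

# The synthetic data generator

The generator emulates the features of dermoscopic data that the pipeline
stages consume, not their photorealism:

* lesions are ellipses with a seeded sinusoidal radial border perturbation
  (amplitude = `border_irregularity`), rasterized by a per-pixel inside test
  so masks are pixel-exact; MEL specs are strictly darker, more irregular
  and more core-shaded than BEN specs, which makes the two classes
  separable by design (a plain intensity threshold already exceeds 80%
  accuracy);
* skin texture is Gaussian pixel noise (sd 4 intensity units, a realistic
  smooth-skin roughness at 8 bits);
* hairs are quadratic strokes 1–4 px thick drawn without anti-aliasing, each
  drawn pixel recorded in a ground-truth mask and forced strictly darker
  than the pixel it covers;
* contrast degradation is a monotone gamma/gain remap; near-duplicates add
  seeded Gaussian noise (sd 1.5 keeps correlation above 0.99, emulating
  repeat acquisitions);
* everything is a pure function of (spec, seed).

What it does **not** model: rulers, gel bubbles, ink markings, vignetting,
multi-lesion frames, camera color profiles, or the morphological diversity
of real lesions. Passing the property suites on these synthetics
demonstrates that the algorithms are implemented correctly and behave as
designed; it does not certify clinical performance on real dermoscopy.

# Desk-scale configurations

The default network specifications match the full-scale design (128×128
classifier input, 192×256 segmentation input, 256×256 contrast patches).
Training such networks is not meaningful on a laptop-scale CPU budget, so
the test suite and the reproduction script train reduced configurations and
state so explicitly:

* classifier: 64×64 input, channels `16,16 | 32,32,32,32 | 64,64`, 32 FC
  units, 15 epochs on 60 images (30 MEL / 30 BEN), evaluated on 20;
* segmentation: 48×64 input (the 3:4 aspect of the full design), channels
  8/12/16/16/16, 24 epochs at learning rate 0.05 on 20 image/mask pairs;
* contrast: 32×32 patches, 16 filters, 24 epochs on patches from 8 clean
  images; evaluated by RMSE against the clean originals on 20 degraded
  images;
* two-arm experiment: 80 hairy/degraded images per seed, 3 seeds, identical
  classifier seed and hyperparameters in both arms; the validation split is
  folded into training since no tuning happens at this scale. The
  experiment's segmentation stage is trained on images that passed through
  the same hair-removal + enhancement front it sees inside the pipeline —
  segmentation operates on enhanced images by design, and a clean-trained
  model faces a distribution shift there. The segmentation quality bar
  (held-out Dice) is measured under the matching clean-train/clean-test
  protocol.

The full-scale defaults are still built and their parameter budgets
asserted; they are simply not trained in the tests.

# Numerical choices and edge cases

* 8-bit storage everywhere, float arithmetic internally, rounding half away
  from zero on write (so closed-form examples are exact).
* Morphology runs on the [0, 1] scale internally (the image library's
  convention) and is rescaled with float dust cleared, so extensivity and
  idempotence hold exactly on integral inputs.
* Cross-entropy clamps probabilities at 1e-12 when a target class receives
  exactly zero probability, with a warning.
* Zero-denominator metrics (e.g. precision with no positive predictions)
  return 0 with a warning; an empty confusion matrix is an error.
* AUC uses the trapezoidal sweep with tied scores grouped, which equals the
  Mann-Whitney rank statistic with ties averaged.
* Constant images have no defined correlation; `pearson_correlation`
  returns 0 with a warning.
* An empty segmentation mask makes `crop_roi` return the full frame with a
  warning, and the pipeline logs a fallback instead of failing the run.
* Batch normalization uses batch statistics during training and running
  averages (momentum 0.1) at inference; the two learnable parameters per
  feature are counted, the running statistics are not.
* Max-pooling requires even spatial dimensions; the classifier enforces
  input sizes divisible by 16 (four pooling stages).

# Known limitations

* The CNN engine is plain single-threaded BLAS; it is deliberately small and
  deterministic rather than fast, and supports exactly the layer types the
  three networks need.
* Hair inpainting blurs texture under wide masks; light-colored hairs are
  not detected.
* The contrast network learns to invert the synthetic gamma/gain family it
  was trained on; nothing is claimed about other degradation families.
* Deduplication is O(n²) in images per class; at real-dataset scale a
  blocking or hashing scheme would be needed in front of it.
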