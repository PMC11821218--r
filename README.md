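# dermocad

Building blocks for a computer-aided diagnosis (CAD) pipeline that
distinguishes melanoma (MEL) from benign (BEN) skin lesions in dermoscopic
images. Dermoscopic frames are routinely degraded by dark hairline artifacts
and poor contrast, and the lesion usually occupies only part of the frame;
`dermocad` implements the full chain that deals with this before and during
classification:

1. **Hairline removal** — grayscale morphological closing with a bank of
   line structuring elements (length 15, orientations 0/45/90/135°), residue
   thresholding at `T = 25`, mask dilation, and inverse-distance-weighted
   inpainting from the nearest unmasked pixels:
   `Close(I) = (I ⊕ SE) ⊖ SE`, `Diff = Close(I) − I`, `Mask = Diff > T`.
2. **Contrast restoration** — a multiscale context aggregation network
   (MCAN) of eight dilated-convolution residual blocks (rates
   2,4,6,8,16,32,64,128; 32 filters each) with learnable adaptive
   normalization `out = μ·x + λ·BN(conv(x))`, trained as a regression
   (MSE) on synthetic gamma/gain degradations of clean images.
3. **Lesion segmentation** — an atrous convolutional network (ACNN): 16
   stride-1 feature layers in 5 blocks with dilation doubling per block
   (1,2,4,8,16), no pooling, per-pixel softmax, weighted cross-entropy with
   inverse pixel-frequency class weights.
4. **Classification** — a compact 11-block CNN (N-DCNN): first conv block of
   8 3×3 kernels, conv groups repeated 2/4/2 times, leaky-ReLU (`s = 0.3`),
   batch norm, max-pooling at group boundaries, ~3.27 M parameters /
   3,080 kernels, trained with SGDM (lr 0.001, momentum 0.99, L2 5e-4) and
   weighted cross-entropy.

Around the networks the package provides dataset preparation (near-duplicate
removal by Pearson correlation > 0.99, stratified 70/10/20 largest-remainder
splitting, minority-class random oversampling, seeded geometric
augmentation), the standard confusion-matrix metric suite
(ACC/PRE/REC/SPE/F1, trapezoidal ROC-AUC, layer-wise parameter counting),
and a **synthetic dermoscopic image generator** with pixel-exact lesion and
hair ground truth, so every stage is testable without any download. The
neural networks run on a small, deterministic CNN engine included in the
package (dilated im2col in C++, BLAS matrix products, exact analytic
gradients verified against numerical differentiation).

Everything is seeded: every generator, training loop and pipeline run is a
pure function of its inputs and seed.

## Worked example

```r
library(dermocad)

# a synthetic hairy lesion with ground truth
g  <- generate_lesion_image(random_lesion_spec("MEL", 96, 96, seed = 3))
hh <- add_hairs(g$image, hair_overlay_spec(n_hairs = 5, thickness_px = 2, seed = 4))

# remove the hairs and score the detection against the known mask
r <- remove_hairlines(hh$image)
dice_coefficient(r$detection_mask, hh$mask)
#> [1] 0.9377828

# metrics from a confusion matrix (TP 1293, FP 126, TN 1050, FN 108)
c_ <- confusion_counts(tp = 1293, fp = 126, tn = 1050, fn = 108)
c(accuracy(c_), precision(c_), recall(c_), specificity(c_), f1_score(c_))
#> [1] 90.92 91.12 92.29 89.29 91.70

# stratified 70/10/20 split with largest-remainder apportionment
idx <- data.frame(path = sprintf("i%d.png", 1:5789), label = "MEL")
table(stratified_split(idx, seed = 1)$split)
#>  test train   val
#>  1158  4052   579
```

The numbers above are what the code prints: hair detection on this seeded
example overlaps the ground-truth hair mask with Dice 0.94, the metric
functions reproduce the percentage row implied by the confusion counts at
two decimals, and a class of 5,789 images splits into exactly 4052/579/1158.

Model training follows the same pattern for all three networks:

```r
tr <- generate_dataset(30, 30, 0, seed = 41, image_size = c(64, 64))
spec <- ndcnn_spec(input_shape = c(64, 64, 3),
                   channel_schedule = c(16, 16, 32, 32, 32, 32, 64, 64),
                   fc_hidden = 32)
fit <- train_ndcnn(ndcnn_model(spec, seed = 3), tr$images, tr$index$label,
                   ndcnn_train_config(epochs = 15, batch_size = 16), seed = 8)
predict(fit, tr$images[[1]])
#> $probabilities
#>          MEL          BEN
#> 9.999998e-01 2.040475e-07
#>
#> $label
#> [1] "MEL"
```

A command-line front end over the same functions lives at
`inst/cli/dermocad.R` (subcommands `synth`, `dehair`, `enhance`, `segment`,
`classify`, `train-*`, `dedup`, `split`, `oversample`, `evaluate`).

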