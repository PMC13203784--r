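---
title: "Methods: the hybrid CNN-Transformer U-Net in lesionseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the hybrid CNN-Transformer U-Net in lesionseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`lesionseg` implements a hybrid residual-CNN / Transformer U-Net for binary
segmentation of breast lesions in 2-D images. The network has four parts:

1. **Residual encoder.** Four stages, each of two residual blocks followed
   by 2x2 max pooling. A residual block is
   `Y = ReLU(BN(Conv3x3(X)))`, `Z = BN(Conv3x3(Y))`, output
   `ReLU(Z + S)`, where the skip `S` is the identity when the channel
   counts match and `BN(Conv1x1(X))` otherwise. Convolution biases are
   disabled throughout the CNN (batch normalization supplies the affine
   terms); the only biased convolution is the output head. Channel widths
   start at `base_channels` (default 32) and double per stage
   (32-64-128-256), while a 256x256 input shrinks to 128, 64, 32, 16.

2. **Bottleneck.** Two residual blocks double the top encoder width
   (256 to 512) at 16x16 resolution. The 512-channel map is then flattened
   row-major into 256 tokens of width 512, learnable positional embeddings
   are added, and the tokens pass through `transformer_layers` (default 4)
   pre-norm Transformer blocks: `z' = z + MHSA(LN(z))`,
   `z'' = z' + FFN(LN(z'))`. Attention is scaled dot-product over 8 heads
   (per-head dimension 512/8 = 64); the FFN widens by `mlp_ratio` (default
   4) with a GELU nonlinearity. With `use_transformer = FALSE` the tokens
   are never formed and the model degrades to a plain residual U-Net -- the
   ablation baseline.

3. **Decoder.** Four blocks of learned upsampling (2x2, stride-2 transposed
   convolution), concatenation with the matching encoder skip, and two
   residual blocks halving the channels (512-256-128-64-32). If the
   upsampled map and the skip disagree in size (odd inputs), the upsampled
   map is bilinearly resampled to the skip's size before concatenation;
   mismatches are aligned, never rejected.

4. **Output head.** A single 1x1 convolution with bias (32 channels to 1;
   exactly 33 parameters) followed by a sigmoid,
   `P = 1 / (1 + exp(-z))`. Masks are produced by thresholding at 0.5;
   the tie at exactly 0.5 is assigned to foreground, so the documented
   threshold is inclusive.

All layers -- including backpropagation through the attention bottleneck --
are implemented in R on top of BLAS matrix multiplication (convolutions as
im2col/GEMM; the backward-data pass reuses the forward routine with
spatially flipped, channel-transposed kernels). This keeps the package
dependency-free of any deep-learning runtime while remaining fast enough
for the reduced-scale experiments below.

### Parameter accounting

`count_parameters()` sums trainable arrays and splits them by name into a
Transformer part (positional embedding plus all Transformer weights) and a
CNN part, so `total = transformer_part + cnn_part` holds by construction.
Under the conventions above the default configuration has 28,712,769
trainable parameters (12,740,608 in the Transformer). Published per-block
totals for this family of architectures vary with unstated conventions
(residual blocks per stage, bias placement, attention widths); the only
per-layer count this package treats as a contract is the output head's 33.

## The training objective

The loss is `total = BCE + (1 - Dice_soft)` with

* `BCE = -mean(y log p + (1-y) log(1-p))`, probabilities clamped to
  `[1e-7, 1 - 1e-7]` before the logarithms;
* `Dice_soft = (2*sum(y*p) + eps) / (sum(p) + sum(y) + eps)`, `eps = 1e-6`
  in numerator and denominator, so empty-vs-empty yields Dice 1. The
  soft Dice is computed over the whole mini-batch.

The BCE term's gradient with respect to the logits simplifies to
`(p - y)/N`; the Dice term chains through `p(1-p)`. Both are implemented
analytically and verified against finite differences in the test suite.

## Training automation

Adam (betas 0.9/0.999, eps 1e-8 -- conventional defaults, as the training
recipe leaves them unstated) with learning rate 1e-4, batch size 4, up to
50 epochs. After every epoch the validation Dice (mean per-image hard Dice
at threshold 0.5) drives two counters:

* **Plateau schedule**: 5 stagnant epochs halve the learning rate
  (factor 0.5) and reset the plateau counter.
* **Early stopping**: 12 stagnant epochs end training.

An epoch is stagnant unless the Dice improves by at least 1e-5 (the recipe
gives no tolerance; a strict `>` on doubles would make patience counters
noise-sensitive). Gradients are clipped to a global L2 norm of 5.0 every
step. The best-validation-Dice epoch, not the last, becomes the returned
checkpoint. Mixed precision is accepted in the configuration for
compatibility but all computation here is double precision.

## Warm-start sequential transfer

`warm_start()` implements incremental weight transfer: parameters (and
normalization buffers) whose hierarchical name AND shape match the
checkpoint are overwritten; everything else keeps its fresh initialization,
mirroring non-strict state-dict loading. A missing checkpoint file is a
defined branch ("Training from scratch"), distinct from a corrupt file
(I/O error). `sequential_transfer()` chains datasets: phase 1 from
scratch, phase k from phase k-1's best checkpoint, identical loss and
hyperparameters in every phase. No forgetting mitigation (no EWC,
rehearsal, or distillation) is applied -- deliberately -- and
`evaluate_previous = TRUE` re-evaluates earlier phases after the chain as a
forgetting diagnostic only. The order in which datasets are chained is the
caller's explicit choice.

## Evaluation protocol

Per-image Dice, IoU, accuracy and F1 (hard masks at threshold 0.5) are
averaged over a split, and each mean carries a 95% percentile-bootstrap
confidence interval over 1000 resamples of the per-image scores
(percentile rather than BCa: the simplest method consistent with the
protocol; deterministic given a seed). Whether published scores of this
kind use soft or hard masks is usually unstated; this package reports
hard-mask metrics, and "per foreground object" averaging is interpreted as
per-image averaging, since no instance-matching procedure is defined for
the alternative reading. Confusion statistics (precision/recall/F1
one-vs-rest per class, macro and weighted averages) are pooled over all
pixels of the split. ROC-AUC uses the tie-aware rank (Mann-Whitney)
formulation; full-resolution pixel ROC is memory-heavy, so at most 1e5
pixels are subsampled with a fixed seed (an exact mode exists and is used
in tests, where the rank AUC is also cross-checked against an independent
ROC implementation).

## Data handling

Images are read with EBImage (PNG/JPEG/TIFF), resized bilinearly to
256x256, scaled to [0, 1], and grayscale is replicated to three channels.
Masks are resized nearest-neighbor so they stay binary; RGB-coded masks
(black background, red/green lesion classes) decode to foreground iff a
pixel is closer to pure red or green than to black, which reduces to
`R > 0.5 | G > 0.5`; grayscale masks threshold at >127 of 255. All mask
classes collapse to binary foreground -- multi-class segmentation is out of
scope.

Splitting is at patient level: patients are shuffled with a seed and
assigned 70/15/15 by cumulative floor rounding with remainders to train
(20 patients give exactly 14/3/3), and every image follows its patient, so
no patient spans two splits.

Two augmentation families sit behind one config, since the reference
protocol describes both small continuous rotations (plus or minus 15
degrees with flips and intensity variation) and right-angle rotations with
scaling; the continuous set is the default "aug" variant. Geometric
transforms are applied identically to image and mask (nearest-neighbor,
re-binarized); intensity jitter is multiplicative, uniform in [0.9, 1.1],
image-only; scale jitter zooms uniformly in [0.9, 1.1] with center-crop or
reflection padding back to size.

## Synthetic phantoms

The phantom generator emulates the statistical character of the four
modalities: ultrasound (dark elliptical lesions on mid-gray background,
multiplicative gamma speckle of shape 4 -- a standard first-order speckle
approximation -- and mild depth shading), histology (20-80 small dark
nuclei on a pale textured background, mask = union of nuclei), mammography
(bright Gaussian-blurred mass on a smooth gradient), and MRI (hyperintense
region on a noisy dark background). The mask is always the generating
geometry rendered before noise, so registration is exact. A synthetic
patient's images share one base geometry with jitter, making patient-level
splitting a real leakage test. Phantoms carry learnable signal -- a reduced
hybrid model overfits 8 of them to Dice 1.0 -- but they are statistically
far simpler than clinical data: no acoustic shadowing, no anatomy, no
annotation noise. Passing tests on phantoms therefore validate the
*mechanics* (shapes, gradients, protocols), not clinical performance, and
the published clinical Dice levels are deliberately not reproduced here.

## Problem sizes and numerical choices

The test and acceptance runs use reduced scales chosen as the package's own
study conditions: the overfit sanity check trains the reduced hybrid model
(base 8, input 64, 2 Transformer layers, ~1.4M parameters) on 8 ultrasound
phantoms for at most 200 Adam steps at learning rate 3e-3 (the default
1e-4 is tuned for full-scale training; a small overfitting probe
legitimately runs hotter), batch 4. The bootstrap coverage study uses 500
Monte-Carlo replicates of n = 30 normal scores with 1000 resamples each.
Full-scale (256x256, base 32) runs appear only as single forward passes for
the shape contracts.

Other numerical choices: batch-norm eps 1e-5 with momentum 0.1 and unbiased
running variance; layer-norm eps 1e-5; GELU in its exact
`x * pnorm(x)` form; He initialization for convolutions, Xavier for
Transformer projections, N(0, 0.02) positional embeddings, unit/zero
batch-norm affine; max-pool ties resolved to the first element in
raster order; bilinear resampling uses the half-pixel-center convention and
is exactly linear, so its backward pass is the transposed map; token order
is row-major and the inverse reshape asserts the same order (round-trip
tested bit-exactly).

## Known limitations

* Phantom realism is intentionally minimal (see above).
* Pooled-pixel AUC subsampling makes AUC stochastic across seeds at very
  large splits (exact mode is available).
* The plain-U-Net baseline is the same code path with the Transformer
  disabled; its internals carry no published shape/count contract.
* Training is CPU-bound R; full-scale, full-dataset training is outside
  the intended envelope -- the package targets method correctness and
  reduced-scale experiments.
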