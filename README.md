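# lesionseg

Transformer-enhanced hybrid U-Net for binary breast-lesion segmentation,
implemented entirely in R.

## The problem

Delineating breast lesions in 2-D medical images (ultrasound, histology,
mammography, MRI) is a binary segmentation task with severe class
imbalance: a small, irregular foreground against a dominant background.
Convolutional encoder-decoder networks capture local texture well but
struggle with long-range shape context; Transformers capture global
structure but discard fine detail. `lesionseg` implements the hybrid of
the two for researchers who want a fully inspectable, dependency-light
reference implementation: a residual U-Net whose bottleneck runs
multi-head self-attention over tokenized feature maps, together with the
full training, transfer-learning and evaluation protocol around it.

## The model

* **Encoder**: 4 stages x 2 residual blocks
  (`ReLU(BN(Conv3x3)) -> BN(Conv3x3)` plus identity/1x1-projected skip,
  final ReLU), channels 32 → 64 → 128 → 256, 2x2 max-pool per stage
  (256² input → 16² bottom map).
* **Bottleneck**: two residual blocks widen 256 → 512 channels; the
  512x16x16 map is flattened row-major into N = 256 tokens of width 512,
  learnable positional embeddings are added, and L = 4 pre-norm
  Transformer blocks (`z' = z + MHSA(LN(z))`, `z'' = z' + FFN(LN(z'))`,
  8 heads, d_k = 64, GELU FFN with 4x expansion) model global context.
  `use_transformer = FALSE` gives the plain residual U-Net ablation.
* **Decoder**: 2x2/stride-2 transposed convolutions, skip concatenation,
  two residual blocks per stage (512 → 256 → 128 → 64 → 32), bilinear
  alignment when sizes disagree.
* **Head**: 1x1 convolution (33 parameters) + sigmoid,
  `P(x,y) = 1 / (1 + exp(-z(x,y)))`, threshold 0.5.
* **Loss**: `L_total = L_BCE + (1 - Dice_soft)` with
  `Dice_soft = (2 Σ y p + ε) / (Σ p + Σ y + ε)`.
* **Training**: Adam (lr 1e-4), ReduceLROnPlateau (factor 0.5, patience
  5), early stopping (patience 12), gradient clipping at global norm 5.0,
  best-validation-Dice checkpointing, and warm-start sequential transfer
  (non-strict name-and-shape state-dict matching) across datasets.
* **Evaluation**: per-image Dice/IoU/accuracy/F1 with 95% percentile
  bootstrap CIs (1000 resamples), pooled one-vs-rest confusion
  statistics, rank-based ROC-AUC.

Every layer, including backpropagation through the attention bottleneck,
is written on top of BLAS matrix operations (im2col/GEMM convolutions) —
no deep-learning runtime is required. Clinical datasets are not needed
either: a synthetic phantom generator emulates the four modalities with
exact ground-truth masks and patient grouping.

## Worked example

Overfit a reduced hybrid model (base 8, 64x64 input, 2 Transformer
layers) on 8 synthetic ultrasound phantoms and evaluate it:

```r
library(lesionseg)

pcfg <- phantom_config("ultrasound", image_size = 64, patients = 8,
                       images_per_patient = 1, seed = 7)
samples <- lapply(1:8, function(i) {
  ph <- generate_phantom(pcfg, seed = 7 * 10007 + i)
  list(image = array(rep(ph$image, 3), c(64, 64, 3)), mask = ph$mask)
})

acfg <- arch_config(base_channels = 8, input_size = 64,
                    transformer_layers = 2)
model <- hybrid_unet(acfg, seed = 1)
count_parameters(model)$total
#> [1] 1399889

fit <- train(model, samples,
             train_config(learning_rate = 3e-3, max_epochs = 100,
                          batch_size = 4, seed = 1),
             max_steps = 200)
evaluate_split(fit$model, samples, seed = 1)
#> Segmentation metric report over 8 images (threshold 0.5 )
#>   dice      0.9999 (0.9997-1.0000)
#>   iou       0.9998 (0.9994-1.0000)
#>   accuracy  1.0000 (0.9999-1.0000)
#>   f1        0.9999 (0.9997-1.0000)
#>   pooled AUC 1.0000
```

The Dice row says the model's predicted masks overlap the exact phantom
geometry almost perfectly on the training phantoms (the point of the
sanity run is that the architecture and its hand-written gradients can fit
the data at all); the interval is the bootstrap CI over per-image scores.

The same functionality is scriptable from a shell via the thin CLI in
`inst/cli/lesionseg` (`generate-data`, `train`, `transfer`, `evaluate`,
`predict`, `run-suite`, `report`).

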