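# daunet — dense-attention U-Net for DWI gland/lesion segmentation

`daunet` is an R implementation of a dense-attention encoder–decoder for
semantic segmentation of 2-D diffusion-weighted MRI (DWI) slices into
background, gland and lesion. It is aimed at methods researchers who want a
fully inspectable, dependency-light reference of this architecture family —
every layer, including all backward passes, is implemented in the package
(C++ via Rcpp/RcppArmadillo), with no deep-learning framework underneath —
together with the complete experimental protocol around it and a synthetic
phantom generator so the whole pipeline runs and is tested without any
clinical data.

## The model

A U-shaped backbone whose contraction path doubles channel widths per stage
(64 → 128 → 256 → 512 → 1024 by default) is extended by three toggleable
components:

- **Dense blocks** in the encoder: stacks of composite functions
  (batch norm → ReLU → 3×3 conv → dropout) in which each layer consumes the
  concatenation of the block input and all previous outputs, closed by a
  1×1 transition back to the stage width.
- **CBAM attention** in the decoder, after each of the two 3×3 conv+ReLU
  steps. Channel attention gates each channel with
  `M_C(F) = σ(MLP(AvgPool(F)) + MLP(MaxPool(F)))`, the MLP
  (`W1·ReLU(W0·x)`, bottleneck C/r, r = 16) shared between both pooled
  descriptors; spatial attention gates each pixel with
  `M_S(F′) = σ(f^{7×7}([AvgPool(F′); MaxPool(F′)]))`. Both apply
  multiplicatively: `F′ = M_C(F) ⊗ F`, `F″ = M_S(F′) ⊗ F′`.
- **GN-ASPP head**: four parallel branches — a 1×1 conv and three 3×3
  dilated convs at rates (6, 12, 18), padding = dilation — each followed by
  group normalization, concatenated and 1×1-projected.

Skips are fused at both the symmetric level and asymmetrically from the
next-deeper encoder stage (bilinear ×2 upsample + 1×1 projection). Training
minimizes per-pixel cross-entropy with Adam (150 epochs by default,
checkpointing on validation loss, early stopping), and evaluation reports
Dice, IoU, accuracy, sensitivity and the 95th-percentile Hausdorff distance
(pooled symmetric, in mm). The protocol is a stratified 70/30 train/test
split with 4-fold cross-validation inside the training set, plus a six-row
ablation grid over the three component toggles.

See `vignettes/dense-attention-segmentation.Rmd` for the full model account,
parameter meanings and design decisions.

## Worked example

Simulate phantoms, train a reduced-width model and run the ablation grid:

```r
library(daunet)

pc <- phantom_config(image_size = 32L, lesion_probability = 0.5,
                     gland_axis_range = c(0.25, 0.4), noise_sd = 0.03,
                     seed = 202L)
ds <- generate_dataset(pc, 6L)
ds[[1]]
#> <image_sample 'phantom_001' 32x32, labels {0,1,2}>

tab <- run_ablation(
  ds,
  network_config(base_channels = 4L, depth = 2L, cbam_reduction = 2L,
                 gn_groups = 2L, dense_layers = 2L, seed = 4L),
  train_config(epochs = 60L, learning_rate = 1e-3, batch_size = 2L,
               early_stop_patience = 60L, checkpoint_dir = tempfile(),
               seed = 6L),
  split_spec(seed = 5L))
tab
#>   use_dense use_cbam use_aspp      dice       iou     hd95 parameters
#> 1     FALSE    FALSE    FALSE 0.9776894 0.9563898 1.000000       2184
#> 2      TRUE    FALSE    FALSE 0.9640028 0.9305078 1.000000       2781
#> 3     FALSE     TRUE    FALSE 0.9282099 0.8676033 1.500000       2414
#> 4     FALSE    FALSE     TRUE 0.9676130 0.9372674 1.000000       2748
#> 5      TRUE     TRUE    FALSE 0.9360346 0.8821013 1.500000       3011
#> 6      TRUE     TRUE    TRUE  0.7199999 0.5627825 6.352163       3575
```

Each row trains the same seed/optimizer/split with one combination of the
dense / CBAM / ASPP toggles (row 1 is the plain fusion U-Net backbone) and
reports mean test-set Dice, IoU and HD95 (mm) for the gland class, plus the
trainable parameter count. At this deliberately tiny smoke scale (six 32×32
phantoms, width-4 network, 60 epochs) the numbers only demonstrate that
every variant trains and evaluates; they say nothing about relative merit on
real data.

The metric layer can be used standalone:

```r
gt <- matrix(0L, 3, 3); gt[1:2, 1:2] <- 1L      # 4-pixel square
pred <- matrix(0L, 3, 3); pred[1:2, 2:3] <- 1L  # shifted one column
cc <- confusion(pred, gt, 1L)
c(dice = dice(cc), iou = iou(cc), accuracy = accuracy(cc),
  sensitivity = sensitivity(cc))
#>        dice         iou    accuracy sensitivity
#>   0.5000000   0.3333333   0.5555556   0.5000000
```

A command-line front-end wraps the same functions
(`inst/cli/daunet <simulate|train|crossval|ablate|evaluate|visualize>`);
every run writes a JSON manifest with the fully resolved configuration and
seeds.

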