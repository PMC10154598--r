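---
title: "Dense-attention encoder-decoder segmentation: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense-attention encoder-decoder segmentation: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`daunet` implements a convolutional encoder-decoder for semantic
segmentation of 2-D diffusion-weighted MRI (DWI) slices into background,
gland and lesion, together with the full experimental protocol around it:
per-image min-max normalization, geometric augmentation, a stratified 70/30
train/test split with 4-fold cross-validation, per-pixel cross-entropy
training with Adam, and an evaluation suite of Dice, IoU, accuracy,
sensitivity and the 95th-percentile Hausdorff distance. Because clinical DWI
with expert masks cannot ship with a package, a synthetic phantom generator
reproduces the statistical structure of such data well enough to exercise
and test every stage end to end.

This vignette records the model, its assumptions, the tunable parameters,
and the design decisions that were genuinely open.

## The network

The backbone is U-shaped. The contraction path has `depth` stages (default
5); stage $i$ operates at $1/2^{i-1}$ resolution and width
$C_i = \mathtt{base\_channels} \cdot 2^{i-1}$, i.e. 64, 128, 256, 512, 1024
with the defaults. Each stage applies two $3\times3$ convolutions with ReLU;
stages are connected by $2\times2$ max-pooling. The expansion path mirrors
this with $2\times2$ up-convolutions that halve the width, concatenation
with encoder features, and two further $3\times3$ conv+ReLU blocks. All
convolutions are zero-padded to preserve spatial size ("same" padding), so
logits align with the input pixel grid and masks need no crop bookkeeping —
this trades the classical valid-convolution trimming for simpler geometry
and is the package's deliberate convention.

Three components extend the backbone; each has an independent toggle so the
model family forms an ablation grid:

**Dense blocks** (`use_dense`). After the two stage convolutions, a
DenseNet-style block of `dense_layers` composite functions (batch
normalization, ReLU, $3\times3$ convolution emitting `growth` channels,
dropout) runs with each layer consuming the concatenation of the block input
and all previous layer outputs. A $1\times1$ transition convolution returns
the concatenation (width $C_i + n \cdot \mathrm{growth}$) to the stage width
so the 64-to-1024 schedule is preserved. The block internals are not pinned
down by the architecture's public description; we chose $n = 4$ layers,
growth $C_i/4$ and dropout 0.1 as the smallest configuration that doubles
the stage's internal width before the transition. Normalization statistics
inside the blocks are computed over the spatial extent of the current
forward call and tracked as running averages for evaluation mode, which
makes training behaviour independent of how samples are batched.

**Convolutional block attention (CBAM)** (`use_cbam`), applied after each of
the two decoder convolutions. Channel attention computes, per channel,
global average- and max-pooled descriptors $F^C_{avg}, F^C_{max}$, passes
both through a shared two-layer perceptron with a $C/r$ bottleneck (ReLU
after the first layer, reduction ratio $r = 16$ by default) and gates the
map with

$$M_C(F) = \sigma\!\big(W_1 \mathrm{ReLU}(W_0 F^C_{avg}) + W_1
\mathrm{ReLU}(W_0 F^C_{max})\big), \qquad F' = M_C(F) \otimes F.$$

Spatial attention stacks the channel-wise mean and max maps into a
2-channel field, applies a $7\times7$ same-padded convolution and a sigmoid,

$$M_S(F') = \sigma\!\big(f^{7\times7}([\mathrm{AvgPool}(F');
\mathrm{MaxPool}(F')])\big), \qquad F'' = M_S(F') \otimes F',$$

where $\otimes$ is elementwise multiplication. Both gates lie strictly in
$(0,1)$, so attention can only attenuate: $|F''| \le |F|$ elementwise, a
property the tests assert.

**Group-normalized ASPP** (`use_aspp`) in the head: four parallel branches —
a $1\times1$ convolution and three $3\times3$ dilated convolutions at rates
(6, 12, 18) with padding equal to dilation — each followed by group
normalization (`gn_groups = 8`), concatenated and projected back by a
$1\times1$ convolution. Group norm is used here instead of batch norm
because its statistics do not depend on batch size, which matters at the
small batches CPU training permits. The rate triple is the conventional
multi-scale choice and divides cleanly into the receptive fields available
at full resolution.

**Skip fusion.** Besides the symmetric skip (encoder stage $s$ into decoder
level $s$), each decoder level receives an *asymmetric* skip from the
next-deeper encoder stage: its output is bilinearly upsampled by 2 and
projected by a $1\times1$ convolution to half the symmetric skip's width
before concatenation. The exact connectivity of multi-level fusion is a
genuinely open design point; one-level-deeper fusion with a light projection
adds multi-scale context at every level for the smallest parameter overhead,
and is applied uniformly (at the deepest level the "next-deeper" stage is
the bottleneck itself). The head prepends three $3\times3$ conv+ReLU layers
before the ASPP module and a final $1\times1$ convolution maps to class
logits; "three convolutions before the pyramid" is our reading of the
architecture's last-layer description and is flagged as an interpretation.

All layers, including every backward pass, are implemented in the package
(C++ kernels via Rcpp/RcppArmadillo; no deep-learning framework is used).
Backward passes are verified against finite differences in the test suite.
Parameters are He-initialized from `network_config(seed=)`, so a
configuration builds bit-identically every time.

## Two single-target modes and a joint mode

Clinically the organ and its lesion are reported separately, so the default
is a pair of binary models: `label_mode = "gland"` merges labels
$\{1, 2\}$ into the foreground (whole organ), `"lesion"` keeps only label 2.
`label_mode = "joint"` trains one 3-class model. The CBAM description's
"2-channel" input is read as describing an intermediate feature map, not the
network input, which defaults to a single DWI slice (`in_channels = 1`).

## Preprocessing and augmentation

Normalization is the per-image linear map
$X_{norm} = (X - X_{min})/(X_{max} - X_{min})$. Per-image (rather than
dataset-global) extrema make every slice span $[0,1]$ regardless of scanner
scaling, and the map is idempotent. A constant slice maps to zeros instead
of erroring so blank padding slices cannot crash a batch pipeline.

Augmentation applies each configured transform *independently* to the
original sample: rotations by $(-10, 0, 45, 60)$ degrees (the $0°$ entry is
the identity copy), one shift per axis direction, and rescales by 0.9 and
1.1 — ten outputs per sample by default. The published augmentation
arithmetic for this family of experiments cannot be reconciled with any
single multiplier without knowing the raw slice counts, so independent
application with a configurable transform list is the package's semantics.
Shift magnitude is unspecified in the protocol; the default is 10% of the
image side. Rescaled outputs are resampled back onto the original canvas
(centre crop for 1.1, background pad for 0.9) so all samples share one
shape for batching. Images are interpolated bilinearly, masks by nearest
neighbour (label alphabet closed by construction); resampling is delegated
to EBImage.

## Split, folds and training protocol

`train_test_split()` assigns `round(0.7 n)` samples to training, stratified
by lesion presence — with lesion-bearing samples a minority (58 of 180
subjects in the emulated cohort), unstratified splits can starve a fold of
lesions. `make_folds()` shuffles once (seeded) and partitions the training
set into 4 folds; each sample validates exactly once. Whether the reported
protocol's held-out 30% also served as CV validation is ambiguous in the
source; the text applies CV to "all training data", and that is what is
implemented: folds are drawn from the training set only.

Training minimizes unweighted per-pixel cross-entropy with Adam
(learning rate $10^{-4}$, default moment constants; only the optimizer name
and the loss are pinned by the protocol, the rest are conventional
defaults). "Trained 150 times" is read as 150 epochs, consistent with the
epoch axes of the associated learning curves. After each epoch validation
loss and IoU are logged; the best-validation parameters are checkpointed and
training stops after 15 epochs without improvement (the protocol names
checkpointing and stopping without detail; validation loss with patience 15
is our choice). Batch size defaults to 4, sized for CPU training. With a
fixed seed, shuffling, dropout and initialization are all deterministic, and
a rerun reproduces the loss curves and metrics byte-for-byte in
single-threaded execution.

## Metrics

For one class, with pixel confusion counts:
$\mathrm{Dice} = 2tp/(2tp+fp+fn)$, $\mathrm{IoU} = tp/(tp+fp+fn)$,
accuracy $=(tp+tn)/N$, sensitivity $= tp/(tp+fn)$; Dice $= 2\,\mathrm{IoU}/
(1+\mathrm{IoU})$ holds as an identity and is asserted numerically. The
95% Hausdorff distance is defined here as the 95th percentile of the
*pooled symmetric* set of boundary-to-boundary nearest-neighbour Euclidean
distances; whether a reported 95%HD is directed or pooled is often left
unstated, and the pooled symmetric form is the common medical-segmentation
convention (both directions and the percentile are configurable).
Boundaries are extracted as the mask minus its 4-connectivity erosion, with
the image border treated as background; isolated pixels are their own
boundary. Pixel spacing defaults to 1 mm.

Degenerate pairs are scoreable by convention: ground truth and prediction
both empty gives Dice = IoU = sensitivity = 1 and HD95 = 0 (a lesion-free
phantom predicted lesion-free is a correct answer); an empty ground truth
with a non-empty prediction gives Dice = 0 and an HD95 flagged invalid
(`hd95_valid = FALSE`), and invalid distances are excluded from aggregation.

## The phantom generator

Each phantom is a rotated ellipse ("gland") of intensity 0.55 on a 0.1
background, with orientation uniform on $[0, \pi)$ and semi-axes uniform in
15-35% of the image side; with probability 58/180 (the emulated cohort's
patient fraction) a disk ("lesion") of intensity 0.9 and radius 20-50% of
the gland's minor semi-axis is placed so that every lesion pixel lies inside
the gland — the centre is rejection-sampled (up to 1000 tries, then the
radius shrinks by 20% and sampling repeats), which guarantees containment on
the pixel grid by construction. Gaussian noise (sd 0.05) is added to the
image only, never the mask, and intensities are clipped to $[0,1]$. The
contrast ordering lesion > gland > background mimics hyperintensity at high
b-values. The whole dataset is a pure function of (config, seed).

What the phantoms deliberately do not model: MR physics (b-values, TE/TR),
3-D anatomy, multi-sequence input, partial-volume boundaries, bias fields,
or realistic lesion morphology. Passing tests on phantoms therefore
demonstrate that the implementation is correct and the pipeline learns and
evaluates as specified — not that the architecture reaches any particular
accuracy on clinical DWI, which would require the private cohort and
GPU-scale training and is explicitly out of scope.

## Numerical choices and problem sizes

Ties in the argmax decision rule resolve to the lower class index, so an
all-zero logit map predicts background. The constant-image normalization
policy returns zeros. Checkpoint compatibility is enforced by a hash of the
architecture configuration (excluding the initialization seed). Percentiles
use R's default quantile definition (type 7).

The test suite and the acceptance script exercise the stack at reduced
scale, chosen so a laptop CPU runs them comfortably: unit checks use depth-2
networks with base width 4 on 32x32 phantoms; the learning-capacity check
uses the published reduced configuration (base 8, depth 3, 64x64, eight
samples, up to 200 epochs, with training halted once training-set Dice
reaches 0.95); determinism and ablation checks run at 2-epoch smoke scale.
The reduction ratio at those widths is lowered (r = 4, or 2 at base width 4)
because r must divide the channel count at every attention site; the
architectural default remains r = 16 at base width 64.

## Known limitations

- Training is single-threaded CPU code; it is meant for method study and
  testing at phantom scale, not for training on clinical volumes.
- Batch statistics in dense blocks are per-forward-call; with batch size 1
  this is equivalent to instance-level normalization, which differs from
  cross-sample batch norm in large-batch regimes.
- The asymmetric fusion wiring is one defensible reading of an
  under-specified design; alternatives (multi-level or bidirectional
  fusion) are not implemented.
- HD95 is 2-D only; volumetric surface distances and average symmetric
  surface distance are out of scope.
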