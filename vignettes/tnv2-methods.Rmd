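---
title: "TurkerNeXtV2 in tnv2: model, training recipe, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TurkerNeXtV2 in tnv2: model, training recipe, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnv2)
```

## The model

TurkerNeXtV2 is a lightweight convolutional classifier built around
*pooling-based attention*: instead of learned token mixing (self-attention)
or large depthwise kernels, the spatial mixing in every block is done by
parameter-free 3×3 average and max pooling, fused through a sigmoid gate.
The intuition comes from plantar-pressure imaging: max pooling responds to
focal load peaks (the hallmark of an osteoarthritic gait), average pooling
summarizes the global load distribution, and their gated product passes only
activations that stand out both locally and globally.

The network has four parts, with the default schedule
F = (96, 192, 384, 768), one TNV2 block per stage:

**Patchify stem.** A 4×4 convolution with stride 4 and 96 output channels
converts the 224×224×3 input into a 56×56×96 grid of patch embeddings `P`.
One batch normalization `B = BN(P)` feeds both branches of a light grouped
inverted bottleneck added residually:

    T1 = Conv1x1_96( GELU( GConv1x1_384( B ) ) ) + B

There is exactly one GELU in the stem. The patchify convolution and its
batch normalization are computed once and shared by the two branches; this
is the parameter-minimal reading of the stem definition and matches the
architecture's single-path block diagram.

**TNV2 block** = pooling-based attention followed by an inverted bottleneck,
both shape-preserving at width F:

    gate  = sigmoid( AvgPool3x3(B) ⊙ MaxPool3x3(B) ),   B = BN(x)
    att   = Conv1x1_F( GELU( AvgPool3x3( [gate, B] ) ) ) + B
    out   = Conv1x1_F( GELU( GConv1x1_4F( BN(att) ) ) ) + att

The fusion of the two pooled maps is the element-wise (Hadamard) product:
the two operands have identical H×W×F shapes, so only the element-wise
reading is shape-consistent, and the architecture's own block description
("element-wise fusion, gated by a sigmoid") confirms it. The gate therefore
lies strictly in (0, 1). `[gate, B]` is depth concatenation with the gate in
the lower channel indices. All 3×3 pools use stride 1 with padding 1, which
is the only reading compatible with the published per-stage shapes
(a TNV2 block maps 56×56×96 to 56×56×96, and so on). The `BN(x)` appearing
three times inside the attention equations is one shared instance per block;
the bottleneck has its own. A block at width F holds exactly three
parameterized convolutions (2F→F, F→4F grouped, 4F→F) and two batch norms:
7F² + 10F trainable parameters.

**Hybrid downsampling.** Between stages, resolution halves and channels
double:

    TD = GELU( [AvgPool2x2,s2(x), MaxPool2x2,s2(x)] + GConv2x2_2F,s2(x) )

The concatenation of the two F-channel pooled maps (average first) is added
element-wise to the 2F-channel strided grouped convolution before a single
GELU. Odd input sizes are a hard error rather than silently padded: with a
224 input every stage is even by construction, and implicit padding would
corrupt the published shape table.

**Head.** Global average pooling flattens the final 7×7×768 tensor to 768
features, one fully connected layer maps to class scores, and a softmax
yields probabilities.

### Grouped-convolution policy and the parameter budget

The architecture specifies *grouped* 1×1 expansions and a grouped 2×2
downsampling convolution but not the group counts. The package fixes
groups = 4 for every 1×1 expansion (stem and TNV2 blocks) and groups = 2 for
the 2×2 downsampling convolutions. With the shared stem normalization and
shared per-block attention normalization described above, this policy gives
**6,332,554** trainable parameters with a 10-class head and **7,093,864**
with a 1000-class head — reproducing the published "~6.3 M" / "~7.1 M"
budget at one-decimal rounding. `count_parameters()` implements the closed
form; `enumerate_parameters()` independently sums the instantiated arrays,
and the two must agree exactly. Only scale and shift of each batch norm are
counted as trainable; running statistics are buffers (the standard
convention, and required to land on the published totals).

```{r params}
count_parameters(tnv2_config(num_classes = 10L))
trace_shapes(tnv2_config(num_classes = 10L))
```

## Numerical conventions

* GELU is exact (`x * pnorm(x)`), not the tanh approximation.
* Batch normalization uses epsilon 1e-5 and running-statistics momentum 0.1
  (biased variance in the normalization, unbiased in the running update).
* Average pooling counts zero padding in its fixed k² divisor; max pooling
  excludes padded positions. Both match the common framework defaults; the
  loop-based oracles in the test suite restate the same conventions
  independently.
* Max-pooling gradient ties resolve to the first window slot in row-major
  order; probability argmax ties resolve to the lowest class index.
* Weights are He fan-in normal (`sd = sqrt(2/fan_in)`), biases zero, batch
  norm scale 1 / shift 0, all drawn deterministically from the config seed.
* Checkpoints round-trip bit-exactly (IEEE doubles are serialized, never
  printed and re-parsed).

Forward and backward passes are implemented as BLAS matrix algebra on a
row-major (image, row, column) × channel layout: 1×1 convolutions are plain
matrix products, k×k convolutions use an im2col gather, pooling windows are
precomputed row gathers. The backward pass of every layer is hand-derived
and was verified against central finite differences at every block during
development; the shipped tests check each block's forward against explicit
loop-based oracles.

## Training recipe

`tnv2_fit()` implements the published recipe as defaults: SGD with momentum
0.9, 30 epochs, batch size 128, learning rate 0.01, L2 penalty 1e-4, and a
randomized stratified 80:20 train/validation split. The momentum update is

    v ← 0.9 v + (g + λ w),   w ← w − lr · v

with the L2 term applied to convolution and fully connected weight matrices
only (biases and batch-norm parameters are decay-free, following the
toolbox default the recipe was taken from). The data are shuffled every
epoch, the last partial batch is used, and the returned checkpoint is the
epoch with the highest validation accuracy (earliest on ties). Cross-entropy
is computed on the softmax outputs. Input images are scaled to [0, 1] with
no mean/std normalization or augmentation — the training description
mentions none.

## The synthetic generator and what it does (not) show

`generate_pressure_images()` emulates weight-normalized pedobarograph
frames: a foot-shaped support region (forefoot/arch/heel ellipses with a
small random pose jitter), a heel-to-toe center-of-pressure ridge with
lateral sway, additive Gaussian background noise, and two loading regimes —
the *osteoarthritis-like* class concentrates load in 1–3 compact Gaussian
hotspots (radius 4–8 px at 224², peak amplitude 0.7–1.0 before
normalization), the *control-like* class spreads comparable load over 4–7
broad bumps (radius 22–34 px, amplitude 0.12–0.22). Every image's total
mass is normalized to the same constant (2.5% of the pixel count), the
analogue of body-weight normalization: the classes differ in *contrast*,
not energy. Generation is a pure function of the seed, and hotspot
coordinates are attached to the set for localization checks.

The generator produces cleanly separable classes by construction — a single
threshold on the image maximum separates them. Passing the training and
Grad-CAM checks on these images therefore demonstrates that the
architecture, gradients, optimizer, and saliency pipeline work end to end;
it says nothing about accuracy on real plantar-pressure data, which depends
on sensor noise, inter-subject variability, and class overlap that the
generator deliberately omits.

## Scaled-down study sizes

The shipped checks exercise training at desk scale: 64 synthetic images
(32 per class), a width-scaled variant with filters (8, 16, 32, 64) at the
full 224×224 input (so the saliency stage keeps the published 7×7
geometry), batch size 16, and otherwise the recipe above, with training
seeds 1–3. These sizes keep a full three-seed study within minutes on one
CPU while leaving every architectural mechanism — all four block types,
grouped convolutions, batch-norm statistics, checkpoint selection — on the
published code path. Validation accuracy in evaluation mode depends on
batch-norm running statistics, which need a few epochs to converge; early
epochs can therefore show chance-level validation accuracy while training
accuracy is already perfect.

## Grad-CAM

`grad_cam()` targets the output of the last TNV2 stage (the last
convolutional representation before pooling). The class score is the
pre-softmax logit; its gradient with respect to the stage activations is
averaged spatially into one weight per channel, the weighted channel sum is
rectified, bilinearly upsampled (align-corners) to the input resolution, and
min-max normalized to [0, 1]. A constant raw map — e.g. an all-zero head —
degenerates to the all-zeros map rather than NaN. Because the gradient is
taken at the logit, the map is invariant to adding a constant to all class
scores. ReLU rectification before normalization follows standard Grad-CAM;
the colormap and blending of the rendered overlay are presentation choices.

## Known limitations

* Evaluation-mode behavior depends on batch-norm running statistics; a
  checkpoint taken very early in training can predict poorly even when
  training accuracy is high.
* Training is CPU-bound R linear algebra: the full-width network trains at
  desk scale only for small datasets. The package validates the full-width
  architecture structurally (shapes, parameter counts, forward pass) and
  trains width-scaled variants.
* The binomial accuracy test treats test items as independent Bernoulli
  trials; with multiple steps per subject this overstates the effective n.
* The accuracy confidence interval is reported with both Wilson and
  normal-approximation methods, which bracket but do not exactly reproduce
  every published interval, whose method is unstated.
* `simulate()`/`residuals()` methods are not provided for the fit object; a
  softmax image classifier admits neither naturally.
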