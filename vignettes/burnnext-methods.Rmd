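---
title: "BurnNeXt: model, attention modules and evaluation protocol"
author: "BurnNeXt authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BurnNeXt: model, attention modules and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BurnNeXt)
```

## The problem

Burn depth determines treatment: superficial (first-degree) burns heal on
their own, while deep dermal and full-thickness burns usually require skin
grafting. Clinically the depths are distinguished largely by colour and
texture — red/pale-pink for superficial, blotchy red/white for deep dermal,
white/brown/deep-red with a leathery or charred appearance for full
thickness. BurnNeXt implements a convolutional classifier for burn
photographs that addresses two tasks over the same images: a three-class
*degree* task (superficial / deep dermal / full thickness) and a binary
*graft* task obtained by collapsing the depth labels into the clinical
decision (graft = deep dermal or full thickness; non-graft = superficial,
see `toBinaryLabels()`).

Clinical burn photographs cannot be redistributed with an R package, so the
package also ships a synthetic image generator that reproduces the one
statistical property the classifier exploits — colour/texture separability of
the three depths — and the whole pipeline (training, fivefold
cross-validation, metric suite) runs end-to-end on generated data.

## The backbone

The classifier is a slimmed 50-layer ResNeXt: a stem convolution followed by
four stages of grouped bottleneck blocks. Each bottleneck computes an
aggregated transform — a sum of $\mathbb{C}$ parallel low-dimensional
transformations $\sum_{i=1}^{\mathbb{C}} \Upsilon_i(\rho)$, realised as a
$1\times1$ reduction, a $3\times3$ *grouped* convolution with cardinality
$\mathbb{C}=32$ (each group is one $\Upsilon_i$), and a $1\times1$ expansion
— and adds it to its input through a residual shortcut,
$x = \rho + \sum_i \Upsilon_i(\rho)$.

Relative to the reference ResNeXt-50 topology the network is slimmed for the
two burn tasks: the stem uses a $5\times5$ kernel with 256 channels
(a large first-layer kernel lowers pixel intensity in the burnt region and
was observed to inflate false negatives on grafts, hence the reduction from
$7\times7$), and the four stage widths shrink to
$(32{:}128)\times3$, $(64{:}256)\times4$, $(256{:}512)\times6$,
$(512{:}1024)\times3$ (inner:output channels × blocks). Activations are
Leaky ReLU throughout (negative-region slope 0.01 by default, configurable),
so negative responses keep a learning signal. The head is global average
pooling, a flatten, and a $k$-way softmax with $k = 3$ (degree) or
$k = 2$ (graft).

`deriveShapes()` prints the resulting trace for a 100×100×3 input:

```{r}
deriveShapes(burnNeXtConfig())
```

### Parameter accounting

Published parameter counts depend on what is counted, so
`countParameters()` makes the convention explicit:

* `"stage_tabulation"` — only the stage-table convolutions, with the grouped
  rule $k_h k_w (C_{in}/g) C_{out}$: no projections, biases, normalisation,
  attention or head. This is the convention under which the slimmed network
  has 4,898,912 ≈ 5×10⁶ weights.
* `"full_backbone"` — additionally the $1\times1$ projection shortcut at
  each stage boundary. Under this convention the reference ResNeXt-50
  backbone has 22,911,680 ≈ 23×10⁶ weights.
* `"all"` — every trainable scalar in the model as built (batch-norm scale
  and shift, attention weights, classifier head).

The conventions are monotone (`all` ≥ `full_backbone` ≥ `stage_tabulation`),
and `parameterBreakdown()` gives per-stage subtotals.

### Numerical conventions the architecture needs

The stage trace 100 → 50 → 25 → 13 → 7 → 4 only exists under a definite
padding rule; we use **"same" padding with ceil-mode output sizes**
($H_{out} = \lceil H/s \rceil$), for convolutions and pooling alike.
Downsampling (stride 2) sits in the first block of the third, fourth and
fifth stages at the $3\times3$ convolution — the standard ResNeXt placement —
because the stage table itself assigns strides only to the stem and its
pool. Shortcuts are the identity where shapes agree and a $1\times1$
projection (with batch norm) where channel count or stride changes. Every
convolution is followed by batch normalisation — the network does not train
reliably without it — but batch-norm parameters are excluded from
`stage_tabulation` counting since stage tables tabulate convolutions only.
Weights are He fan-in initialised ($\sigma = \sqrt{2/\text{fan-in}}$) from a
seeded stream, so builds are reproducible.

## Attention

A residual/channel/spatial attention block is appended to the output of each
bottleneck stage (the module itself does not prescribe a placement;
the attachment set is configurable per stage).

**Residual attention.** The stage output is channel-shuffled by the
$(N,S)$ transpose-interleave (`channelShuffle()`), partitioned into $N$
groups of $S = 4$ subgroups, and each subgroup $s$ is rotated by $s$ quarter
turns (`rotateSubgroup()`; the $r\pi/2$ rotation matrix acting on spatial
coordinates about the grid centre — on a discrete even-sized grid this is
the usual transpose-and-flip array rotation). All subgroups pass through one
*shared* $3\times3$ convolution $K$, and subgroups $s>0$ are modulated by
the base response: $y_0 = K(x_0)$, $y_s = K(g_s(x_s)) \odot y_0$. Rotating
feature subgroups before a shared kernel cheaply diversifies the orientation
statistics each group sees.

**Channel attention.** Per group $G^n$, spatial global average pooling
feeds two fully connected layers shared across groups — a ReLU squeeze of
width $\lceil (C/N)/r \rceil$ (reduction $r = 16$, the customary
squeeze-excitation default; the source architecture leaves it open) and a
sigmoid excitation — giving per-channel gates $C^n \in (0,1)^{C/N}$.

**Spatial attention.** Channel-wise average and max maps are stacked into a
$2\times H\times W$ descriptor, a $3\times3$ convolution reduces it to one
map, and its sigmoid gates every channel per position. The defining equation
is ambiguous between *adding* and *concatenating* the two descriptors, but
only concatenation matches the stated $2\times H\times W$ shape, so
concatenation is the default and the summed variant is available as
`variant = "sum"`. Likewise, "GAP" necessarily means *spatial* pooling in
the channel-attention formula (it must yield a $C/N$-vector) and *channel*
pooling in the spatial-attention formula (it must yield $1\times H\times W$
maps); `globalPool()` exposes both axes explicitly.

**Width preservation inside the network.** The literal group-summed form
$C = \sum_n (C^n \odot G^n)$ maps $C$ channels to $C/N$, which would break
the residual trunk if applied in-network. The in-network block therefore
applies the per-group gates and reassembles the groups by concatenation
(width-preserving); the literal group-summed operation is still exported
unchanged as `applyChannelAttention()` with its $C/N$-channel contract.

All gates are sigmoid outputs, so attention never amplifies:
spatial attention is a contraction in max-norm, which the tests assert.

## Local response normalisation

`localResponseNorm()` implements divisive normalisation across a sliding
channel window: $b^i_{u,v} = a^i_{u,v} / (t + \alpha \sum_j (a^j_{u,v})^2)^\beta$
with the sum over the $n$ channels nearest $i$ (clipped at the edges). The
constants are unspecified in the source description, so the canonical
AlexNet setting $t = 2$, $n = 5$, $\alpha = 10^{-4}$, $\beta = 0.75$ is the
default, all configurable. The same ambiguity holds for placement; the
default places LRN after the stem and after the first bottleneck stage. The
formula's summand is read as the *activation* $a^j_{u,v}$ (the printed
symbol collides with the constant $\alpha$; the activation is the only
dimensionally sensible reading).

## Training engine

No deep-learning framework is available to R in this environment, and the
network *is* the package's subject, so the forward and backward passes are
implemented in the package itself: grouped convolutions via im2col + BLAS
GEMM in C++ (with a direct whole-batch GEMM fast path for $1\times1$
convolutions), fused batch-norm/Leaky-ReLU and LRN kernels, max-pooling with
argmax routing, and the attention block with its full product-rule backward.
Every backward pass is verified against central finite differences in the
test suite.

Loss is categorical cross-entropy on the softmax head (the natural choice
for $k$-way classification; the source names none). The optimizer default is
Adam at the stated initial learning rate $10^{-3}$ (the source names no
optimizer; SGD with momentum 0.9 is selectable), mini-batch 32, with
seeded shuffling so runs are bit-reproducible. "Training iterations" are
read as epochs.

**Batch-norm statistics at inference.** Running means/variances are kept as
exponential moving averages during training; after the last optimisation
step `trainModel()` replaces them with exact training-set moments (one extra
forward pass, combining within-batch variances and between-batch mean spread
by the law of total variance). On the small datasets this package targets,
the moving average alone leaves a visible train/inference mismatch.

Softmax is computed with max-subtraction (mathematically identical, stable
for large logits).

## Synthetic data

`generateDataset()` emulates only what the classifier exploits: each image
is a beige skin-tone background (fixed anchor with per-image brightness
jitter) carrying one elliptical lesion (semi-axes uniform in 26–33 px,
jittered centre, random orientation) filled according to the class palette:

* *superficial* — uniform mix of red and pale pink with a smooth
  low-frequency field;
* *deep dermal* — blotchy red/white patches from a thresholded smooth noise
  field;
* *full thickness* — radial white/deep-red/brown gradient with a dark
  charred centre.

Gaussian pixel noise (sd 8 of 255 by default) is added and clipped. The
whole dataset is a pure function of its `synthConfig()` (one seeded stream
drives geometry, palette mixing and noise), which the tests assert at the
byte level. Class balance defaults to uniform — the source material reports
only a total image count, never per-class counts.

The default palettes, mixing ranges and lesion-size range were calibrated
once, while the generator was designed, against its stated contract: the
three classes must be separable enough that a trivial whole-image
mean-colour centroid classifier reaches 95% on a default-size set (the
suite asserts this), which in turn guarantees the network-training criterion
is achievable. The binding constraints are the spread of the lesion area
(which scales every class's colour shift) and the per-image variance of the
deep-dermal blotch ratio; the defaults keep both small.

What the generator does **not** emulate: anatomy, lesion boundary
irregularity, lighting gradients, specular highlights, occlusions, skin-tone
diversity, or any intra-class depth continuum. Passing the packaged training
criterion therefore demonstrates that the implementation can learn
colour/texture-separable classes end-to-end — not that it reaches any
particular accuracy on clinical photographs.

## Augmentation

The default set is horizontal flip, vertical flip, and rotations by ±30°
(the published augmentation list names four transforms; the figure
accompanying it also shows quarter-turn rotations, which are available as
`rot90`/`rot270`). Flips and quarter turns are exact pixel permutations and
conserve the image histogram; ±30° rotations use bilinear interpolation with
**reflect-padding fill** — constant-fill corners would inject a strong
label-independent cue into augmented sets. Because four transforms can only
multiply a dataset by five, `oversampleDataset()` additionally supports
randomised flip/rotation chains to reach an arbitrary target count.
`runCVExperiment()` augments *training folds only*, so validation images are
never augmented copies of training images, and records that policy in its
run log.

## Evaluation

`kfoldSplit()` produces stratified folds (per-class 80/20) so small sets
cannot lose a class from a validation fold; folds are disjoint, their union
is the full id set, and assignment is deterministic under the seed.
`metricsFromCM()` computes one-vs-rest accuracy, precision, recall, F1,
sensitivity and specificity per class (in percent) plus the macro average
and the overall (trace) accuracy. Two conventions deserve note:

* recall and sensitivity are the same quantity ($TP/(TP+FN)$) and are
  reported identically by construction;
* specificity defaults to the standard true-negative rate $TN/(TN+FP)$;
  the printed form $TN/(TP+TN)$ that appears in some reports is preserved
  verbatim as `mode = "paper_literal"` so published tables can be audited.
  On the worked binary example TP=9, FP=1, FN=1, TN=9 the two give 90%
  and 50% respectively.

Zero-denominator cells are `NA` with a flag naming the cell — never silently
zero. Macro averaging is unweighted one-vs-rest (the source reports single
numbers without naming a scheme). `rocCurve()` builds one-vs-rest ROC
curves with tie-grouped thresholds and trapezoid AUC; the tests pin it to
the Mann–Whitney rank statistic.

## Problem sizes used by the packaged experiments

The packaged tests and the acceptance script run the pipeline at sizes
chosen for a single CPU: 600 synthetic images (200 per class, 100×100),
one stratified 80/20 split, 10 epochs at mini-batch 32, and the half-width
backbone variant `burnNeXtHalfConfig()` (all widths halved, cardinality 16
so each grouped path keeps its per-group width; attention and LRN at their
default placements). The half-width choice is recorded in the run log the
acceptance script prints. Unit tests exercise the same code paths at toy
scale (1/8–1/16 width, 16–25 px inputs).

## Known limitations

* The synthetic criterion bounds what can be claimed: clinical accuracy is
  out of reach without the clinical dataset and full-scale training.
* Attention provides only local feature dependencies; no non-local or
  transformer-style attention is included.
* The residual identity (zeroed bottleneck ⇒ output equals input) holds
  exactly on the non-negative orthant; the Leaky ReLU that follows the
  residual addition rescales negative entries by its slope.
* The model name inherited from the source architecture contains "GAN", but
  no adversarial component is described there and none is implemented.
* Single-CPU training in R/C++ is orders of magnitude slower than a GPU
  framework; the engine is written for correctness, auditability and
  CPU-scale experiments, not production training.
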