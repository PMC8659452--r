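---
title: "Auditing lightweight flower detectors: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing lightweight flower detectors: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomdet)
```

## The problem

Estimating the flowering stage of a citrus orchard comes down to counting
flowers and buds in canopy images. One-stage detectors of the YOLOv4 family
do this well, but the full model (~64 M parameters) is too heavy for the
edge devices mounted in orchards, which motivates a family of lightweight
variants: replacing the CSPDarknet53 backbone with MobileNetv3, rewriting
the feature-fusion ("neck") convolutions as depthwise-separable pairs, and
shrinking to the two-head tiny layout. `bloomdet` implements this design
space as *declarative layer graphs* with exact analytic parameter and FLOP
accounting, together with every data-side component the workflow needs —
annotation interchange, IoU-distance anchor clustering, Cutout/Mosaic
augmentation, VOC-style evaluation, per-image counting — and a small native
runtime so the whole pipeline can be exercised end to end on synthetic
scenes.

## Architecture graphs and parameter accounting

A graph is an ordered tibble of layer nodes (convolution, batch norm,
activation, pooling, upsampling, concatenation, residual add, channel
slice, squeeze-excite scaling), each carrying its channel geometry. The
accounting conventions are the ones under which the published ablation
counts reproduce exactly:

* only trainable values are counted: convolution weights
  $H_k W_k \cdot (D_i/\mathrm{groups}) \cdot D_o$, batch-norm scale and
  shift ($2 D_o$; running statistics are state), dense layers
  $D_i D_o + D_o$;
* a convolution followed by batch norm carries no bias; the final $1\times1$
  head predictors carry bias and no batch norm;
* squeeze-excite blocks count their two biased $1\times1$ projections.

Under these conventions `build_architecture()` reproduces the published
inventory exactly:

| variant | configuration | parameters |
|---|---|---|
| `yolov4` | 2 classes, 3 anchors/head | 63,943,071 |
| `yolov4_dw` | 2 classes, separable fusion network | 35,690,655 |
| `yolov4_tiny` | 20-class transfer configuration | 5,918,006 |
| `improved` | MobileNetv3-Large backbone, 2 classes | 11,309,039 |

Three of the four counts are not fully pinned by a name like "tiny" or
"+dw" alone, so the concrete configurations were *recovered from the
printed numbers* and are now fixed in the builders:

* **`yolov4_dw`** separates every $3\times3$ convolution of the SPP, PANet
  and head-stem sections into depthwise $3\times3$ + pointwise $1\times1$
  pairs (each batch-normalised and activated, biases absent), and *also*
  rewrites the two $1\times1$ upsample-branch convolutions as separable
  blocks. Without the upsample rewrite the total lands 8,448 parameters
  low — exactly the two depthwise stages $9\cdot512 + 2\cdot512$ and
  $9\cdot256 + 2\cdot256$ — which pins that design detail.
* **`yolov4_tiny`**: no two-class separable composition of the tiny neck
  reaches the printed count (an exhaustive grammar search over SPP
  placement, block widths, head styles and bias conventions gets no closer
  than a few times $10^4$). The count is, however, *exactly* the standard
  CSPDarknet53-tiny graph with plain two-head neck and 20-class heads:
  the base-without-predictors total is 5,860,256, predictors add
  $770 \cdot 3(5+C)$, and solving $770 \cdot 3(5+C) = 57{,}750$ gives
  $C = 20$ — an integer solution only for the PascalVOC class count used
  for transfer learning. The printed tiny row therefore describes the
  off-the-shelf VOC-pretrained tiny model, and that is the configuration
  the package attaches to the published number. A genuine 2-class tiny
  with separable neck is available as `yolov4_tiny_dw` (4,048,458
  parameters) and is the variant used for smoke training.
* **`improved`** uses the MobileNetv3-Large feature hierarchy (width 1.0,
  squeeze-excite with `make_divisible(exp/4, 8)` squeeze channels, h-swish)
  tapped at the 40-, 112- and 160-channel stages (strides 8/16/32); the
  final $160\to960$ expansion convolution of the classifier head is *not*
  part of the detector. The taps feed the separable neck through the
  $1\times1$ adapters that open each fusion block; here the upsample
  convolutions stay plain $1\times1$ — both details are pinned by the
  printed total.

`count_parameters()` returns a per-node ledger and per-section subtotals,
and `build_runtime_model()` materialises every tensor the graph declares,
giving an independent runtime check: allocated weights must equal the
ledger total exactly, for every variant.

Weight sizes are reported as fp32 MiB, $4 \cdot \text{params} / 2^{20}$:
243.9 → "244 MB" and 136.1 → "136 MB" for the first two rows, a 44%
saving from the separable rewrite. The printed sizes of the tiny and
MobileNetv3 rows are not $4\times$ their parameter counts (weight files
typically embed optimiser or statistic state), so only the first two are
treated as arithmetic facts.

## FLOP model

`flops_estimate()` propagates spatial dimensions symbolically and counts
multiply-adds: $H_o W_o H_k W_k (D_i/\mathrm{groups}) D_o$ per convolution.
A standard convolution costs $H_i W_i D_i D_o H_k W_k$; its separable
replacement $H_i W_i D_i H_k W_k + H_i W_i D_i D_o$, giving the classical
ratio $1/D_o + 1/(H_k W_k)$ in the large-image limit — about $1/9$th for
the $3\times3$ kernels that dominate these networks. (A variant of this
ratio sometimes circulates with $H_i W_i$ in place of $H_k W_k$ in the
denominator; that form does not follow from the per-layer costs, and the
package uses the standard derivation.)

## Anchor clustering

Anchor boxes are clustered with Lloyd iterations under the distance
$d = 1 - \mathrm{IoU}_{wh}$, where $\mathrm{IoU}_{wh}$ places both boxes at
a common corner: Euclidean distance would let large boxes dominate, while
IoU is scale-aware. Design choices:

* **k-means++ seeding** under the same distance, with a fixed seed, gives
  reproducible, well-spread initialisations.
* **Median centroid updates** (per dimension) are the default — the
  width–height distribution of field boxes is long-tailed and the median
  is robust to it; the mean is available as a switch.
* An **emptied cluster** is re-seeded from the box farthest from its
  anchor; assignment ties break toward the lower anchor index.
* The quality score is Avg IoU: the mean over boxes of the best IoU to any
  anchor. Every reported Avg IoU is recomputable from the returned anchors
  (`avg_iou()`), and tests enforce that equality.

For choosing $k$, the Avg IoU curve over $k = 2..10$ (best of 10 restarts)
is nondecreasing and concave, so "the point with the largest slope" read
literally would always pick the smallest $k$. `select_k_elbow()` therefore
operationalises the rule as the knee: the $k$ whose forward slope *drops*
the most relative to the preceding step, ties toward smaller $k$. The
shipped default anchor file (`citrus_anchors()`: 23x22, 42x39, 64x62,
104x84, 165x141 at 608 px, $k = 5$) is a fixed configuration constant; it
cannot be recomputed here because the imagery behind it was never
deposited.

Whether clustering should run in original-image or network-input
coordinates is ambiguous in the field; the package clusters at network
input scale (boxes rescaled to 608 first), which is the scale the anchors
are consumed at.

## Augmentation

* **Cutout** blanks one axis-aligned square (default $100\times100$,
  fill 0) with its centre uniform over the image, so border squares clip —
  the original Cutout formulation. Boxes are *never* edited: the operation
  simulates foliage occlusion, and an occluded flower is still a flower.
  A fully covered box is deliberately retained.
* **Mosaic** splits the canvas at a random point (30–70%), scale-jitters
  (upward only, so each quadrant is fully covered), shifts
  hue/saturation/value, and composites four images; boxes are transformed,
  clipped to their quadrant, and dropped below 20% visible area — the drop
  threshold is a package convention.
* The plan-based ops (`augment_plan()`) include axis flips *and*
  arbitrary-angle rotation as separate ops, since "random angle flipping"
  is ambiguous; rotation replaces each box by the axis-aligned hull of its
  rotated corners.

## Synthetic scenes

`generate_scene()` emulates the statistical structure of orchard imagery —
green textured canopy, bright five-petal rosettes ("flower"), small pale
ellipses ("bud"), partial foliage occlusion, controllable density and
luminosity — with exact ground truth: each box is the pixel extent of its
rendered blob, so boxes are tight by construction, and occluded objects
stay annotated. Density presets (sparse $\le 10$ boxes, medium 11–30,
dense $> 30$) quantify strata that field studies usually leave qualitative;
they are package conventions. What the scenes do **not** emulate: real
petal texture and specularity, blur, perspective, within-class shape
variety, or annotation noise. Passing tests on these scenes demonstrates
that the pipeline is implemented correctly, not that any accuracy level
carries over to orchard imagery.

## Training at smoke scale

The runtime implements forward and backward passes natively (im2col
convolutions in C++, everything else in R), so training needs no external
framework. The loss follows the YOLOv4 family: CIoU on assigned boxes,
binary cross-entropy objectness, binary cross-entropy class terms. Details
that matter:

* **Assignment**: each ground truth goes to its best width–height-IoU
  anchor overall, plus any anchor with IoU $\ge 0.5$ (multi-scale
  assignment); first assignment wins on cell collisions.
* **Ignore band**: unassigned predictions whose decoded box overlaps any
  object above 0.7 IoU are excluded from the negative objectness term;
  positives are weighted $3\times$ against the ~100:1 negative majority.
* **CIoU gradients** are taken by central differences per positive box
  (4 evaluations of a closed-form scalar); positives are few, so this is
  cheap and immune to algebra slips in the rather involved analytic
  derivative.
* **Optimisation**: Adam (moment rates 0.9/0.999, the default — at a few
  hundred iterations it converges far faster than SGD with momentum, which
  remains available as a switch), global-norm gradient clipping at 10,
  cosine-annealed learning rate with a 5% linear warmup, He-normal
  initialisation, objectness biases started at $-3$.
* **Batch normalisation**: batch statistics drive training; since the
  exponentially averaged running statistics (momentum 0.03) lag badly
  after a short run at batch 2, training ends with a *precise-BN* pass
  that replaces them by equal-weighted batch statistics aggregated over
  the training images before any inference-mode evaluation.

The reference protocol (608 px, batch 32, 75,000 iterations, initial rate
0.001, Mosaic on) is the default `train_config()`; it is far beyond a
single CPU. The package's own study sizes, chosen to exercise every
component end to end, are those of `smoke_benchmark()`: the two-head
separable variant at 160 px on 40 easy scenes (two large well-separated
flowers and one large bud each), batch 2, 300 iterations, Adam at peak
rate 0.003, box-loss gain 3. Under those conditions validation mAP@0.5
reliably exceeds 0.5 — a functionality floor demonstrating the learning
loop works, not a statement about field accuracy.

## Evaluation

Matching is the VOC protocol: detections in descending confidence, each
matched to the highest-IoU unmatched same-class ground truth of the same
image at threshold 0.5 (`mAP@0.5`), ties toward the lower index. AP is the
area under the monotone (all-point interpolated) precision envelope — the
plain integral $\int P\,dR$ — with the VOC-2007 11-point variant behind a
switch; mAP is the exact arithmetic mean over classes and
$F_1 = 2PR/(P+R) = 2TP/(2TP+FP+FN)$. Precision at zero recall is reported
as 1 by convention; this affects curve display only. The flowering-rate
statistic `flower_share` $= n_{flower}/(n_{flower}+n_{bud})$ is an
operational package convention (undefined, and reported as `NA`, for empty
images).

## Known limitations

* The runtime is single-threaded and eager; it is a verification and
  smoke-training engine, not a production trainer.
* Training supports standard and depthwise convolutions (all shipped
  variants); exotic group counts are rejected at model build.
* The synthetic scenes are deliberately simple; see above for what that
  does and does not establish.
* The tiny row of the published inventory is reproduced under its
  transfer-learning class count, as the arithmetic demands; a two-class
  tiny detector should use `yolov4_tiny` / `yolov4_tiny_dw` and will not
  match that printed total.
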