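---
title: "Quantifying shiitake stick browning: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying shiitake stick browning: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stickvision)
```

## The measurement problem

Shiitake cultivation sticks are bagged cylinders of substrate colonised by
mycelium. As the substrate matures, the initially white mycelial surface
pigments brown; growers stage sticks as pre-, mid- or post-browning and use
the browned fraction of the surface as the maturity indicator. Photographs
are taken against uniform red or green backdrops under varying exposure, and
the plastic bag adds specular streaks. Two factors make naive colour
thresholding unreliable: browning patch boundaries are diffuse colour
gradients rather than edges, and the substrate texture is itself beige-brown.

`stickvision` splits the measurement into two supervised stages: first
isolate the stick (so the background can never contaminate the denominator),
then segment browning within the stick only.

## Stage 1: contour extraction and staging

The contour network is a single-stage anchor-free instance segmenter. Design
choices, with the reasoning where the design space was open:

* **Backbone.** Five levels with widths 16/32/48/96/160; each stage is one
  downsampling block plus two repeat blocks. Every block is a minimalist
  "VanillaNet-style" unit — grouped 3×3 convolution (2 groups), batch norm,
  and a dynamic ReLU (a channel-wise gate `max(a_c x, b_c x)` with learned
  slopes, initialised to plain ReLU) — with no residual additions, attention
  or pyramid modules. Downsampling uses 2×2 max pooling.
* **No SPPF.** The spatial-pyramid-pooling block usually closing such
  backbones is removed; the wider grouped-convolution stages stand in for
  its receptive-field growth. An SPPF implementation remains available
  behind `use_sppf = TRUE` for the heavier comparison variant.
* **Neck and heads.** A PAN-style neck (plain 3×3 convolutions) feeds three
  pyramid levels (strides 8/16/32). Each level carries decoupled box and
  class branches (one 3×3 convolution to half the input width, then a 1×1
  projection) and a 1×1 mask-coefficient head; a prototype head on the
  finest level produces 16 shared mask prototypes at 1/4 resolution.
  Instance masks are sigmoid-activated linear combinations of prototypes.
* **Ghost head.** In the VG configuration every 3×3 convolution in the box,
  class and prototype branches becomes a GhostConv: a primary convolution
  producing half the output channels and a cheap depthwise 3×3 generating
  the rest, concatenated. With ratio 2 this almost halves those weights.
* **Budget constraints.** The reference architecture is specified only up to
  its printed parameter totals, so the remaining width freedom was resolved
  against them: the standard-head variant holds 1,700,413 parameters (1.7 M)
  and the Ghost-head VG variant 1,519,513 (1.5 M).

Training uses a deliberately simple single-positive assignment (the cell
containing the box centre on every level is positive), binary cross-entropy
for classification over all cells, an L1 loss on log-distances for the box
at positives, and BCE + Dice between the positive cell's assembled mask and
the ground truth at prototype resolution. Mask coefficients are supervised
at the positive cell of *every* level, so whichever cell survives
non-maximum suppression at inference carries trained coefficients.
Inference letterboxes the image (aspect-preserving, grey fill), thresholds
class confidence (default 0.25), applies class-agnostic NMS (IoU 0.7), and
projects masks and boxes back to image coordinates.

## Semi-automatic browning annotation

Training labels for stage 2 come from a scribble-driven pixel classifier
rather than exhaustive hand masks. Per ROI pixel an 18-channel feature
vector is assembled, in this order: RGB; HSV; difference-of-Gaussians of the
luminance at scale pairs (1,2), (2,4), (4,8); local histogram entropy
(radius 4, 64 bins, in bits); six membrane projections (a 19×19 line kernel
rotated through 6 evenly spaced angles, reduced by sum/mean/max/min/median/
std) capturing the longitudinal surface texture; and the radius-2
neighbourhood mean and standard deviation of luminance. All filters use
reflective borders. The scale and window defaults follow common
trainable-segmentation practice; the operators themselves were fixed, their
parameters were not stated, and these values are this package's choice.

A random forest (100 trees, √F features per split, unlimited depth, seeded)
is fitted on the scribbled pixels only; prediction is restricted to the ROI
and connected components below 20 px are removed as speckle. The classifier
stores a hash of the feature recipe and refuses feature stacks built under a
different recipe. Two open points resolved here: features are computed on
the ROI crop (removing background interference is the point of the two-stage
design), and "neighbourhood analysis" is implemented as local mean/std —
a reconstruction, not an attested choice.

## Stage 2: RS-UNet

The browning segmenter is a U-shaped encoder–decoder:

* **Encoder** — ResNet50-style bottleneck stages (widths 256/512/1024/2048
  at full scale). The *optimised* encoder replaces the classic 7×7 stem with
  (a) a dual-branch input adapter: a 3×3 RGB branch to 16 channels, an edge
  branch applying a 3×3 convolution to the image minus its 3×3 average
  pooling (a high-pass texture signal), and a 3×3 fusion convolution from
  the 32 concatenated channels to 64 (19,392 parameters, all with biases);
  followed by (b) a triple-3×3 stem 64→32→32→64 whose first convolution
  has stride 2. Max pooling completes the 4× entry downsampling, as in the
  classic stem.
* **Decoder** — four levels of bilinear 2× upsampling and skip fusion. The
  deepest level concatenates 2048 + 1024 = 3072 channels and fuses them with
  a *grouped* 3×3 convolution (2 groups), letting colour-like and
  texture-like channel groups be modelled separately at half the weight
  cost; the two middle levels use depthwise-separable convolutions
  (depthwise 3×3 + pointwise 1×1, batch norm after both); the top level is a
  plain 3×3 block. Channel-wise (spatial) dropout at p = 0.3 acts on the
  final two decoder levels during training. A 3×3 refinement block (48→80)
  and a biased 1×1 projection produce full-resolution browning logits.
* **Spatial attention** — on every skip connection: channel-wise max and
  mean maps are concatenated, passed through a biased 7×7 convolution
  (7·7·2 + 1 = 99 parameters) and a sigmoid, and the resulting map gates the
  skip features multiplicatively.

**Parameter accounting.** Batch normalisation follows every convolution
except final projections, and its affine terms are counted. Decoder widths
(1024, 544, 224, 48) and the 80-channel refinement head are the free
quantities; they were fixed so that the assembled totals land on the
reference budgets at printed precision: baseline 61,115,537 (61.12 M),
full RS-UNet 38,923,773 (38.92 M), a 36.31 % reduction. One published
ablation row implies a spatial-attention delta of tens of thousands of
parameters, which no literal max/mean + 7×7 + sigmoid gate can produce
(99 per skip); this package implements the literal construction and absorbs
the difference in the decoder widths rather than inventing unstated layers.

Training minimises BCE + Dice (equal weights) with Adam. The stated
full-scale recipe (AdamW at 10⁻⁴, batch 4, 1024×448 inputs) is exposed as
defaults; Adam without weight decay is used, which at zero decay is the same
update.

## Metrics and conventions

Mask precision, recall, F1 and IoU are pixel-set ratios; box precision and
recall use greedy confidence-ordered one-to-one matching at IoU ≥ 0.5
(an exhaustive optimal matcher is available behind `method = "hungarian"`;
both are compared in the tests). Empty denominators follow explicit
conventions: an empty prediction scores precision 1 against an empty truth
and 0 otherwise (mirrored for recall); the IoU of two empty masks is 1;
with no predictions, precision is vacuously 1 and recall 0. Both micro
(pooled-pixel) and per-image averaging are meaningful; the implementation
reports per-pair scores and leaves aggregation to the caller, because
published per-image means are generally not the harmonic-mean identity of
the pooled scores. Complexity audits report convolution FLOPs under both
the multiply–accumulate and the 2-operation conventions, labelled as such,
since either may be meant by a printed GFLOPs figure.

The browning ratio uses the ROI mask area as its denominator (not the
unwrapped stick surface, which a single view cannot see). The pigmentation
heatmap is one minus normalised luminance, min–max scaled within the
browning mask (a zero-range region maps to 0.5) — a visualisation
reconstruction, not a colorimetric model.

## Synthetic fixtures

No reference imagery is deposited, so all tests run on a seeded generator
producing rounded-rectangle stick silhouettes with band-limited substrate
texture, soft-edged elliptical browning blobs grown until the browning
ratio lands within ±0.02 of a nominal target (the last blob's radius is
bisected), red/green backdrops, exposure gains {0.8, 1.0, 1.25} and optional
diagonal glare streaks. Stage conventions tie the label to the ratio band
(pre < 0.10, mid 0.30–0.60, post > 0.70). The generator exercises the
stated difficulty factors — fuzzy boundaries, substrate/browning colour
similarity, glare — but makes no claim of statistical similarity to real
sticks: passing tests demonstrate that the pipeline's machinery is correct
and trainable, not that real-world accuracy figures transfer.

## Numerical choices and test-scale profiles

* Augmentation: each enabled transform is included independently with
  probability 0.5; magnitudes are drawn uniformly from their sets
  (rotations ±10°/±15°, brightness/contrast ±3/5/7 % about the channel
  mean, exposure ±8 % gain, saturation ±3 % on HSV-S, Gaussian noise at 1 %
  of full scale). Rotation keeps the original frame, filling with the median
  border colour; masks resample nearest-neighbour. Splitting happens before
  augmentation so variants of one original share a split.
* Dataset splits round half-up per validation/test set with the remainder
  to train (3,762 ids at 8:1:1 give 3,010/376/376).
* Polygons use the even-odd rule at 0-based pixel centres, (x = column,
  y = row); mask-to-polygon tracing follows the 0.5 iso-contour.
* Both classic and triple stems downsample with 2×2/stride-2 max pooling in
  the compute path (the usual 3×3/stride-2 entry pool touches no weights, so
  every audited count is unchanged).
* He-normal initialisation; Adam (β = 0.9/0.999, ε = 10⁻⁸); batch-norm
  momentum 0.1; evaluation mode uses running statistics.
* Test-scale profiles shrink widths (multiplier 0.25 for stage 1, 0.125 for
  stage 2) and run on 64×64 scenes; overfit checks use 4 scenes and at most
  200 (stage 1) / 300 (stage 2) full-batch steps, and the end-to-end check
  trains both stages on a 6-scene corpus. These sizes were chosen as the
  smallest at which the learning behaviour is unambiguous.

## Known limitations

* The networks run on a purpose-built dense autograd engine; it is exact
  (finite-difference-validated) but tuned for test-scale profiles, not for
  full-scale training.
* Ratios are reported per view; a single photograph cannot integrate over
  the cylinder, and multi-view aggregation is left to the caller.
* The stage label comes from the stage-1 classifier, never from ratio
  thresholds, so label and ratio can disagree near band boundaries.
* Scene realism is limited: no 3-D geometry, no camera noise model, no
  mixed backgrounds.
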