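# stickvision

Quantifies the browning maturity of shiitake (*Lentinula edodes*) cultivation
sticks from RGB photographs. During substrate maturation the white mycelial
surface of a stick pigments progressively brown; the fraction of the stick
surface that has browned is a practical maturity indicator. `stickvision`
measures it with a two-stage machine-vision pipeline:

1. **Contour stage** — a lightweight anchor-free instance-segmentation
   network (VanillaNet-style grouped-convolution backbone, GhostConv
   segmentation head, no spatial-pyramid pooling block) detects the stick,
   classifies its maturity stage (pre / mid / post browning) and produces a
   pixel mask, from which the region of interest (ROI) is cropped.
2. **Browning stage** — RS-UNet, a ResNet50-encoder U-Net with a dual-branch
   input adapter and triple-3×3 stem, a hybrid grouped/depthwise-separable
   decoder with 30 % spatial dropout, and spatial attention on every skip
   connection, segments browning pixels inside the ROI.

The headline quantity is the **browning area ratio**

    ratio (%) = 100 · |browning ∩ ROI| / |ROI|,

reported per image together with the stage label and a pigmentation-intensity
heatmap. Around the networks the package provides:

* a **semi-automatic annotation engine**: an 18-channel per-pixel feature
  stack (RGB + HSV, difference-of-Gaussians at three scale pairs, local
  histogram entropy, rotated line-kernel "membrane" projections,
  neighbourhood mean/std) classified by a random forest trained on sparse
  user scribbles;
* a **seeded synthetic scene generator** with exact ground truth (the
  reference imagery is not public), emulating stick silhouettes on red/green
  backdrops, substrate texture, soft-edged browning patches, plastic-bag
  glare and exposure variation;
* a **metric suite** (mask precision/recall/F1, IoU, mIoU, box
  precision/recall at IoU ≥ 0.5) with explicit empty-set conventions, plus
  parameter/FLOP complexity audits;
* a small **tape-based autograd engine** (R with Rcpp convolution kernels)
  on which both networks are built and trained.

## Architecture budgets

The full-scale networks reproduce the reference parameter budgets exactly at
the printed precision:

| model | parameters |
|---|---|
| ResNet50-U-Net baseline | 61,115,537 (61.12 M) |
| RS-UNet (all three improvements) | 38,923,773 (38.92 M, −36.31 %) |
| VanillaNet-backbone stage-1 variant | 1,700,413 (1.7 M) |
| VG stage-1 model (Ghost head, no SPPF) | 1,519,513 (1.5 M) |

## Worked example

Train both stages on a small synthetic corpus and quantify browning
end-to-end (test-scale profiles; a few minutes on one CPU):

```r
library(stickvision)
set.seed(7)

scenes <- generate_corpus(6, seed = 7, canvas = c(64, 64))
cfg <- pipeline_config(
  stage1 = contour_model_config(width_multiplier = 0.25,
                                input_size = c(64, 64), activation = "relu"),
  stage2 = rsunet_config(width_multiplier = 0.125),
  stage2_input = c(64, 64), seed = 7)

s1 <- train_stage("contour",  scenes, cfg, steps = 250, seed = 7)
s2 <- train_stage("browning", scenes, cfg, steps = 200, seed = 7)

reports <- run_two_stage(s1$model, s2$model,
                         lapply(scenes, function(b) b$image), cfg)
data.frame(id    = sapply(reports, `[[`, "image_id"),
           stage = sapply(reports, `[[`, "stage"),
           ratio = round(sapply(reports, `[[`, "ratio_percent"), 2),
           truth = round(100 * sapply(scenes, `[[`, "achieved_ratio"), 2))
```

which prints (stage labels from the stage-1 classifier; `truth` is the
generator's exact ground-truth ratio):

```
              id stage ratio truth
1  scene_001_pre   pre  4.81  4.65
2  scene_002_mid   mid 36.80 37.57
3  scene_003_mid   mid 50.52 52.79
4  scene_004_mid   mid 48.38 48.57
5  scene_005_mid   mid 41.52 40.46
6 scene_006_post  post 78.34 81.15
```

Every reported ratio is within a few percentage points of the ground truth,
and all six stage labels are correct. A thin command-line front end over the
same functions ships in `inst/cli/stickvision.R`
(`generate-fixtures`, `train-contour`, `train-browning`, `infer`,
`annotate`, `audit`).

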