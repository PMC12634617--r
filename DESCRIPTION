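Package: stickvision
Title: Two-Stage Machine Vision for Quantifying Browning of Shiitake Cultivation Sticks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the browning maturity of shiitake (Lentinula edodes)
    cultivation sticks from RGB photographs. Implements a two-stage pipeline:
    a lightweight anchor-free instance-segmentation network (VanillaNet-style
    grouped-convolution backbone, GhostConv segmentation head) extracts the
    stick contour and maturity stage, and an attention-augmented
    encoder-decoder (RS-UNet: ResNet50-style encoder with a dual-branch input
    adapter and triple 3x3 stem, hybrid grouped/depthwise decoder, spatial
    attention on skip connections) segments browning regions inside the stick
    ROI. Includes a random-forest semi-automatic annotation engine driven by
    difference-of-Gaussians, local-entropy and membrane-projection pixel
    features, a seeded synthetic scene generator with exact ground truth, a
    segmentation metric suite (IoU, mIoU, mask precision/recall), browning
    area-ratio reporting with pigmentation-intensity heatmaps, and
    model-complexity audits. Networks are built on a small tape-based
    automatic-differentiation engine with Rcpp convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    randomForest,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
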