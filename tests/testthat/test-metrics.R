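# Metric suite: pixel-set scores against a brute-force oracle, detection
# matching, browning ratios, heatmaps and complexity audits.

brute_scores <- function(P, G) {
  tp <- 0; fp <- 0; fn <- 0; un <- 0
  for (i in seq_along(P)) {
    if (P[i] == 1 && G[i] == 1) tp <- tp + 1
    if (P[i] == 1 && G[i] == 0) fp <- fp + 1
    if (P[i] == 0 && G[i] == 1) fn <- fn + 1
    if (P[i] == 1 || G[i] == 1) un <- un + 1
  }
  list(precision = if (tp + fp == 0) as.numeric(sum(G) == 0) else tp / (tp + fp),
       recall = if (tp + fn == 0) as.numeric(sum(P) == 0) else tp / (tp + fn),
       iou = if (un == 0) 1 else tp / un)
}

test_that("mask scores equal the brute-force pixel oracle exactly", {
  set.seed(21)
  for (i in 1:100) {
    P <- matrix(rbinom(256, 1, runif(1, 0.05, 0.9)), 16)
    G <- matrix(rbinom(256, 1, runif(1, 0.05, 0.9)), 16)
    got <- mask_scores(P, G)
    want <- brute_scores(P, G)
    expect_identical(got$precision, want$precision)
    expect_identical(got$recall, want$recall)
    expect_identical(got$iou, want$iou)
  }
})

test_that("mask scores cover the worked example and edge conventions", {
  P <- matrix(0, 4, 4); G <- matrix(0, 4, 4)
  P[1, 1:4] <- 1; P[2, 1:2] <- 1          # |P| = 6
  G[1, 2:4] <- 1; G[2, 4] <- 1            # |G| = 4, |P & G| = 3
  s <- mask_scores(P, G)
  expect_equal(s$precision, 0.5)
  expect_equal(s$recall, 0.75)
  expect_equal(s$iou, 3 / 7, tolerance = 1e-12)

  full <- matrix(1, 3, 3)
  expect_equal(unlist(mask_scores(full, full)[c("precision", "recall", "iou")]),
               c(precision = 1, recall = 1, iou = 1))
  empty <- matrix(0, 3, 3)
  expect_equal(mask_scores(empty, empty)$iou, 1)
  expect_equal(mask_scores(empty, full)$precision, 0)
  expect_equal(mask_scores(empty, full)$recall, 0)
  disA <- matrix(0, 3, 3); disA[1, 1] <- 1
  disB <- matrix(0, 3, 3); disB[3, 3] <- 1
  expect_equal(mask_scores(disA, disB)$iou, 0)
  expect_error(mask_scores(matrix(0, 2, 2), matrix(0, 3, 3)), "differ")
})

test_that("IoU is symmetric, bounded, and 1 iff masks are equal", {
  set.seed(22)
  for (i in 1:25) {
    P <- matrix(rbinom(64, 1, 0.4), 8)
    G <- matrix(rbinom(64, 1, 0.4), 8)
    expect_identical(mask_scores(P, G)$iou, mask_scores(G, P)$iou)
    iou <- mask_scores(P, G)$iou
    expect_true(iou >= 0 && iou <= 1)
    if (iou == 1) expect_identical(P, G)
  }
})

test_that("mean IoU averages per-class values", {
  expect_equal(mean_iou(c(1.0, 0.5)), 0.75)
  expect_equal(mean_iou(0.37), 0.37)
  expect_equal(mean_iou(c(3 / 7, 1, 0)), 0.47619, tolerance = 1e-5)
  expect_error(mean_iou(numeric(0)), "empty")
})

test_that("box precision counts greedy confidence-ordered matches", {
  tr <- lapply(1:3, function(i)
    list(box = c(10 * i, 10, 10 * i + 8, 18)))
  preds <- c(lapply(1:3, function(i)
    list(box = c(10 * i + 1, 10, 10 * i + 8, 18), confidence = 1 - i / 10)),
    list(list(box = c(70, 70, 78, 78), confidence = 0.5)))
  expect_equal(box_precision(preds, tr), 0.75)
  expect_equal(box_recall(preds, tr), 1)

  same <- lapply(tr, function(t) c(t, list(confidence = 0.9)))
  expect_equal(box_precision(same, tr), 1)
  expect_equal(box_precision(list(), tr), 1)   # vacuous precision
  expect_equal(box_recall(list(), tr), 0)
})

test_that("greedy matching agrees with exhaustive optimal matching on small cases", {
  set.seed(23)
  for (case in 1:50) {
    np <- sample(0:5, 1); nt <- sample(0:5, 1)
    preds <- lapply(seq_len(np), function(i)
      list(box = random_box(), confidence = runif(1)))
    tr <- lapply(seq_len(nt), function(i) list(box = random_box()))
    g <- box_precision(preds, tr, method = "greedy")
    h <- box_precision(preds, tr, method = "hungarian")
    expect_gte(h, g - 1e-12)   # optimal matching never scores below greedy
  }
})

test_that("browning ratio counts clipped pixels in percent of the ROI", {
  roi <- matrix(0, 40, 40); roi[3:27, 3:42 - 2] <- 1   # 1000 px
  expect_equal(sum(roi), 1000)
  br <- matrix(0, 40, 40)
  br[cbind(sample(3:27, 463, TRUE), sample(3:40, 463, TRUE))] <- 0   # build exactly 463
  idx <- which(roi == 1)[1:463]
  br[idx] <- 1
  r <- browning_ratio(br, roi)
  expect_equal(r$ratio_percent, 46.3)
  expect_equal(r$browning_pixels, 463L)

  expect_equal(browning_ratio(roi, roi)$ratio_percent, 100)
  expect_equal(browning_ratio(matrix(0, 40, 40), roi)$ratio_percent, 0)
  expect_error(browning_ratio(br, matrix(0, 40, 40)), "no stick region")

  # browning outside the ROI is clipped
  br2 <- br; br2[30:40, ] <- 1
  expect_equal(browning_ratio(br2, roi)$ratio_percent, 46.3)

  # joint translation invariance and monotonicity
  sh <- function(m) rbind(matrix(0, 2, 40), m[1:38, ])
  expect_equal(browning_ratio(sh(br), sh(roi))$ratio_percent, 46.3)
  br3 <- br; br3[which(roi == 1 & br == 0)[1:10]] <- 1
  expect_gte(browning_ratio(br3, roi)$ratio_percent, 46.3)
})

test_that("pigment heatmaps are monotone in darkness and masked", {
  px <- array(200, c(10, 10, 3))
  px[6:10, , ] <- 60                      # dark lower half
  img <- stick_image("h", px, "mid")
  mask <- matrix(1, 10, 10)
  h <- pigment_heatmap(img, mask_raster("h", mask))
  expect_gt(mean(h[6:10, ]), mean(h[1:5, ]))

  uni <- pigment_heatmap(stick_image("u", array(90, c(6, 6, 3)), "mid"),
                         mask_raster("u", matrix(1, 6, 6)))
  expect_true(all(uni == 0.5))

  part <- matrix(0, 10, 10); part[1:3, 1:3] <- 1
  hp <- pigment_heatmap(img, mask_raster("h", part))
  expect_true(all(hp[part == 0] == 0))

  expect_warning(z <- pigment_heatmap(img, mask_raster("h", matrix(0, 10, 10))),
                 "empty")
  expect_true(all(z == 0))
})

test_that("complexity audit reports MACs, the 2-op convention and sizes", {
  m <- assemble_rsunet(rsunet_config(width_multiplier = 0.125))
  a <- complexity_audit(m, c(64, 64))
  expect_identical(a$params, count_parameters(m))
  expect_equal(a$flops_2x, 2 * a$flops_mac)
  expect_gt(a$serialized_size_mb, 0)

  # single 3x3 convolution 3->16 at 640x640: 16*3*9*640*640 MACs
  single <- conv_bn(3, 16, k = 3, bias = TRUE, bn = FALSE, act = "none")
  a2 <- complexity_audit(single, c(640, 640))
  expect_equal(a2$flops_mac, 176947200)
  expect_equal(a2$params, 448L)
})
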