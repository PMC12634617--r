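# Semi-automatic annotation: scribble handling, forest training and
# browning-label prediction.

separable_fixture <- function() {
  # brown patch on white: trivially colour-separable
  px <- array(245, c(40, 40, 3))
  px[10:25, 8:30, 1] <- 120
  px[10:25, 8:30, 2] <- 70
  px[10:25, 8:30, 3] <- 30
  gt <- matrix(0, 40, 40)
  gt[10:25, 8:30] <- 1
  img <- stick_image("sep", px, "mid")
  roi <- mask_raster("sep", matrix(1, 40, 40))
  list(img = img, roi = roi, gt = gt)
}

pick_scribbles <- function(gt, roi, n = 50, seed = 9) {
  with_seed <- stickvision:::with_seed
  H <- nrow(gt)
  with_seed(seed, {
    pos <- which(gt == 1 & roi == 1)
    neg <- which(gt == 0 & roi == 1)
    torc <- function(idx) cbind((idx - 1) %% H, (idx - 1) %/% H)
    scribble_set("sep", torc(sample(pos, n)), torc(sample(neg, n)))
  })
}

test_that("scribble invariants are enforced", {
  expect_error(scribble_set("a", rbind(c(1, 1)), rbind(c(1, 1))), "overlap")
  expect_error(scribble_set("a", matrix(numeric(0), 0, 2), rbind(c(1, 1))),
               "at least one")
  s <- scribble_set("a", rbind(c(1, 2)), rbind(c(3, 4)), "manual")
  f <- tempfile(fileext = ".json")
  write_scribbles(s, f)
  s2 <- read_scribbles(f)
  expect_equal(s2$positive_pixels, s$positive_pixels)
  expect_equal(s2$negative_pixels, s$negative_pixels)
})

test_that("a colour-separable fixture trains to perfect scribble accuracy", {
  fx <- separable_fixture()
  st <- build_feature_stack(fx$img, fx$roi, feature_recipe())
  scr <- pick_scribbles(fx$gt, fx$roi$values)
  clf <- fit_pixel_classifier(st, scr, n_trees = 50, seed = 1)
  expect_equal(clf$train_accuracy, 1.0)

  pred <- predict_browning_labels(clf, st, min_component_px = 0)
  expect_gte(mask_scores(pred$values, fx$gt)$iou, 0.95)

  # determinism under the seed
  clf2 <- fit_pixel_classifier(st, scr, n_trees = 50, seed = 1)
  pred2 <- predict_browning_labels(clf2, st, min_component_px = 0)
  expect_identical(pred$values, pred2$values)

  expect_error(fit_pixel_classifier(st,
    scribble_set("sep", rbind(c(1, 1)), rbind(c(50, 1))), seed = 1),
    "outside")
})

test_that("prediction is confined to the ROI and refuses recipe mismatches", {
  fx <- separable_fixture()
  half_roi <- fx$roi$values
  half_roi[, 21:40] <- 0
  roi2 <- mask_raster("sep", half_roi)
  st <- build_feature_stack(fx$img, roi2, feature_recipe())
  scr <- pick_scribbles(fx$gt * half_roi, half_roi, n = 30)
  clf <- fit_pixel_classifier(st, scr, n_trees = 50, seed = 2)
  pred <- predict_browning_labels(clf, st)
  expect_true(all(pred$values <= half_roi))

  other <- build_feature_stack(fx$img, roi2,
                               feature_recipe(neighborhood_radius = 3))
  expect_error(predict_browning_labels(clf, other), "different recipe")
})

test_that("small connected components are removed by the cleanup threshold", {
  fx <- separable_fixture()
  # paint two large browning blobs and one 5-pixel speck
  px <- array(245, c(40, 40, 3))
  gt <- matrix(0, 40, 40)
  paint <- function(rows, cols) {
    px[rows, cols, 1] <<- 120; px[rows, cols, 2] <<- 70; px[rows, cols, 3] <<- 30
    gt[rows, cols] <<- 1
  }
  paint(3:14, 3:14)       # 144 px
  paint(22:33, 20:33)     # 168 px
  paint(18, 2:6)          # 5 px speck
  img <- stick_image("blobs", px, "mid")
  roi <- mask_raster("blobs", matrix(1, 40, 40))
  st <- build_feature_stack(img, roi, feature_recipe())
  scr <- pick_scribbles(gt, roi$values, n = 40, seed = 3)
  clf <- fit_pixel_classifier(st, scr, n_trees = 50, seed = 3)
  cleaned <- predict_browning_labels(clf, st, min_component_px = 20)
  lab <- EBImage::bwlabel(t(cleaned$values))
  expect_equal(max(lab), 2)

  raw <- predict_browning_labels(clf, st, min_component_px = 0)
  lab_raw <- EBImage::bwlabel(t(raw$values))
  expect_gte(max(lab_raw), 3)
})

test_that("classifier persistence round-trips", {
  fx <- separable_fixture()
  st <- build_feature_stack(fx$img, fx$roi, feature_recipe())
  clf <- fit_pixel_classifier(st, pick_scribbles(fx$gt, fx$roi$values),
                              n_trees = 30, seed = 4)
  f <- tempfile(fileext = ".rds")
  save_pixel_classifier(clf, f)
  clf2 <- load_pixel_classifier(f)
  p1 <- predict_browning_labels(clf, st)
  p2 <- predict_browning_labels(clf2, st)
  expect_identical(p1$values, p2$values)
})
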