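# Stage-1 contour model: architecture constraints, decoding contracts and
# ROI extraction.

test_that("full-scale variants land on their printed parameter budgets", {
  vg <- count_parameters(assemble_contour_model(contour_model_config(
    ghost_head = TRUE, use_sppf = FALSE)))
  vnb <- count_parameters(assemble_contour_model(contour_model_config(
    ghost_head = FALSE, use_sppf = FALSE)))
  expect_equal(round(vg / 1e6, 1), 1.5)
  expect_equal(round(vnb / 1e6, 1), 1.7)
  expect_lt(vg, vnb)
})

test_that("parameter count is monotone in width and in added modules", {
  counts <- vapply(c(0.25, 0.5, 1), function(w)
    count_parameters(assemble_contour_model(contour_model_config(
      width_multiplier = w))), 0L)
  expect_true(all(diff(counts) > 0))

  base <- contour_model_config(ghost_head = FALSE, use_sppf = TRUE)
  nosppf <- contour_model_config(ghost_head = FALSE, use_sppf = FALSE)
  ghost <- contour_model_config(ghost_head = TRUE, use_sppf = FALSE)
  c1 <- count_parameters(assemble_contour_model(base))
  c2 <- count_parameters(assemble_contour_model(nosppf))
  c3 <- count_parameters(assemble_contour_model(ghost))
  expect_lt(c2, c1)   # removing SPPF reduces parameters
  expect_lt(c3, c2)   # swapping the head to GhostConv reduces them further
})

test_that("forward pass obeys the shape contract across sizes and batches", {
  set.seed(41)
  for (sz in c(64L, 320L)) {
    cfg <- contour_model_config(width_multiplier = 0.25,
                                input_size = c(sz, sz), activation = "relu")
    m <- nn_materialize(assemble_contour_model(cfg))
    for (N in if (sz == 64L) c(1L, 2L) else 1L) {
      tp <- tape_new()
      r <- m$fwd(tp, op_leaf(tp, array(runif(sz * sz * 3 * N),
                                       c(sz, sz, 3, N))), FALSE)
      for (i in 1:3) {
        d <- dim(tp_val(tp, r$scales[[i]]$cls))
        expect_equal(d, c(sz / c(8, 16, 32)[i], sz / c(8, 16, 32)[i], 3, N))
      }
      expect_equal(dim(tp_val(tp, r$protos))[c(1, 2, 4)], c(sz / 4, sz / 4, N))
    }
  }
})

test_that("an untrained model stays silent on blank images at high threshold", {
  blank <- stick_image("blank", array(128, c(64, 64, 3)))
  for (s in 1:5) {
    set.seed(s)
    m <- nn_materialize(assemble_contour_model(test_contour_config()))
    expect_length(predict_instances(m, blank, confidence_threshold = 0.99), 0)
  }
})

test_that("predictions are confidence-sorted with boxes inside the image", {
  set.seed(42)
  m <- nn_materialize(assemble_contour_model(test_contour_config()))
  img <- overfit_scenes()[[2]]$image
  inst <- predict_instances(m, img, confidence_threshold = 0.05, iou_nms = 0.9)
  if (length(inst) > 1) {
    confs <- vapply(inst, function(i) i$confidence, 0)
    expect_true(all(diff(confs) <= 0))
  }
  H <- dim(img$pixels)[1]; W <- dim(img$pixels)[2]
  for (i in inst) {
    expect_true(i$box[1] >= 0 && i$box[2] >= 0 &&
                i$box[3] <= W && i$box[4] <= H)
    expect_true(i$box[1] < i$box[3] && i$box[2] < i$box[4])
    expect_true(i$class_id %in% 0:2)
  }
})

test_that("ROI extraction crops to the mask bounding box with offsets", {
  px <- array(seq_len(10 * 10 * 3), c(10, 10, 3))
  img <- stick_image("roi", px / max(px) * 255)
  full <- mask_raster("roi", matrix(1, 10, 10))
  r <- extract_roi(img, full)
  expect_identical(r$offset, c(0L, 0L))
  expect_identical(r$image$pixels, img$pixels)

  sq <- matrix(0, 10, 10)
  sq[3:6, 4:7] <- 1                      # rows 2-5, cols 3-6 zero-based
  r2 <- extract_roi(img, mask_raster("roi", sq))
  expect_identical(r2$offset, c(2L, 3L))
  expect_equal(dim(r2$image$pixels)[1:2], c(4L, 4L))
  expect_identical(r2$image$pixels, img$pixels[3:6, 4:7, ])

  expect_error(extract_roi(img, mask_raster("roi", matrix(0, 10, 10))),
               "no ROI")
})

test_that("contour training loss decreases from the start", {
  set.seed(43)
  m <- nn_materialize(assemble_contour_model(test_contour_config()))
  log <- train_contour(m, overfit_scenes()[1:2], steps = 25, lr = 2e-3)
  expect_true(all(is.finite(log$loss)))
  expect_lt(log$loss[25], log$loss[1])
})
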