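# Annotation parsing, rasterisation, splitting and augmentation.

triangle_doc <- function(label = "1") {
  sprintf('{"imagePath":"im1","shapes":[{"label":"%s","points":[[1,1],[4,1],[2,4]],"shape_type":"polygon"}]}',
          label)
}

test_that("Labelme documents parse into polygon annotations", {
  a <- parse_polygon_annotation(triangle_doc())
  expect_length(a$polygons, 1)
  expect_equal(nrow(a$polygons[[1]]), 3)
  expect_equal(a$labels, "mid")

  empty <- parse_polygon_annotation('{"imagePath":"x","shapes":[]}')
  expect_length(empty$polygons, 0)

  two <- parse_polygon_annotation(paste0(
    '{"imagePath":"im2","shapes":[',
    '{"label":"0","points":[[0,0],[3,0],[3,3]]},',
    '{"label":"2","points":[[5,5],[8,5],[8,8],[5,8]]}]}'))
  expect_length(two$polygons, 2)
  expect_equal(two$labels, c("pre", "post"))

  expect_error(parse_polygon_annotation('{"shapes":[{'), "malformed")
  expect_error(parse_polygon_annotation(
    '{"shapes":[{"label":"7","points":[[0,0],[1,0],[1,1]]}]}'),
    "permitted labels")
  expect_error(parse_polygon_annotation(
    '{"shapes":[{"label":"1"}]}'), "points")
})

test_that("polygon rasterisation follows the even-odd pixel-centre rule", {
  rect <- structure(list(image_id = "r",
                         polygons = list(cbind(x = c(1, 4, 4, 1),
                                               y = c(1, 1, 3, 3))),
                         labels = "mid"), class = "polygon_annotation")
  m <- polygon_to_mask(rect, 6, 6)
  # oracle: brute-force even-odd test at all 36 pixel centres
  oracle <- matrix(0, 6, 6)
  for (r in 0:5) for (c in 0:5)
    oracle[r + 1, c + 1] <- pip_oracle(c, r, rect$polygons[[1]]) * 1
  expect_identical(m$values, oracle)
  expect_equal(sum(m$values), 6)

  whole <- structure(list(image_id = "w",
                          polygons = list(cbind(x = c(-1, 6, 6, -1),
                                                y = c(-1, -1, 6, 6))),
                          labels = "mid"), class = "polygon_annotation")
  expect_true(all(polygon_to_mask(whole, 6, 6)$values == 1))

  none <- structure(list(image_id = "n", polygons = list(), labels = character(0)),
                    class = "polygon_annotation")
  expect_true(all(polygon_to_mask(none, 6, 6)$values == 0))

  degen <- structure(list(image_id = "d",
                          polygons = list(cbind(x = c(1, 2), y = c(1, 2))),
                          labels = "mid"), class = "polygon_annotation")
  expect_error(polygon_to_mask(degen, 6, 6), "3 vertices")
})

test_that("contour tracing round-trips rectangle masks exactly", {
  v <- matrix(0, 12, 12)
  v[4:9, 3:10] <- 1
  m <- mask_raster("rt", v)
  back <- polygon_to_mask(mask_to_polygons(m), 12, 12)
  expect_equal(mask_scores(back, m)$iou, 1)
})

test_that("dataset splitting is deterministic, exhaustive and follows the rounding rule", {
  s <- split_dataset(sprintf("id%02d", 1:10), c(0.8, 0.1, 0.1), seed = 0)
  expect_equal(lengths(s[c("train_ids", "val_ids", "test_ids")]),
               c(train_ids = 8L, val_ids = 1L, test_ids = 1L))

  big <- split_dataset(sprintf("s%04d", 1:3762), c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(lengths(big[c("train_ids", "val_ids", "test_ids")]),
               c(train_ids = 3010L, val_ids = 376L, test_ids = 376L))

  s2 <- split_dataset(sprintf("id%02d", 1:10), c(0.8, 0.1, 0.1), seed = 0)
  expect_identical(s, s2)

  # partition property over all corpus sizes up to 500
  for (n in c(1:50, seq(60, 500, 20))) {
    sp <- split_dataset(as.character(seq_len(n)), c(0.8, 0.1, 0.1), seed = n)
    ids <- c(sp$train_ids, sp$val_ids, sp$test_ids)
    expect_length(ids, n)
    expect_false(anyDuplicated(ids) > 0)
  }

  expect_error(split_dataset(c("a", "a", "b"), c(0.8, 0.1, 0.1)), "duplicate")
})

disk_scene <- function(H = 64) {
  v <- matrix(0, H, H)
  ctr <- (H - 1) / 2
  for (r in 1:H) for (c in 1:H)
    if ((r - 1 - ctr)^2 + (c - 1 - ctr)^2 <= (0.35 * H)^2) v[r, c] <- 1
  img <- array(120, c(H, H, 3))
  img[, , 1] <- img[, , 1] + 60 * v
  list(image = stick_image("disk", img, "mid"), mask = mask_raster("disk", v))
}

test_that("augmentation transforms behave geometrically and photometrically", {
  d <- disk_scene()
  off <- augmentation_policy(rotations = numeric(0),
                             brightness_contrast = numeric(0),
                             noise_fraction = 0, horizontal_flip = FALSE,
                             exposure = numeric(0), saturation = numeric(0))
  out <- augment_pair(d$image, d$mask, off, draw_seed = 5)
  expect_identical(out$image$pixels, d$image$pixels)
  expect_identical(out$mask$values, d$mask$values)

  # determinism: identical draws give bit-identical outputs
  pol <- augmentation_policy()
  a <- augment_pair(d$image, d$mask, pol, draw_seed = 3)
  b <- augment_pair(d$image, d$mask, pol, draw_seed = 3)
  expect_identical(a, b)

  # horizontal flip maps column j to W - 1 - j and is an involution
  flip_only <- augmentation_policy(rotations = numeric(0),
                                   brightness_contrast = numeric(0),
                                   noise_fraction = 0, horizontal_flip = TRUE,
                                   exposure = numeric(0), saturation = numeric(0))
  flipped <- NULL
  for (s in 1:20) {
    cand <- augment_pair(d$image, d$mask, flip_only, draw_seed = s)
    if (!identical(cand$mask$values, d$mask$values) ||
        !identical(cand$image$pixels, d$image$pixels)) {
      flipped <- cand
      break
    }
  }
  # the disk is symmetric; use an asymmetric marker to observe the flip
  marked <- d$mask$values
  marked[30, 5] <- 1
  mm <- mask_raster("disk", marked)
  got_flip <- FALSE
  for (s in 1:20) {
    cand <- augment_pair(d$image, mm, flip_only, draw_seed = s)
    if (!identical(cand$mask$values, marked)) {
      expect_identical(cand$mask$values, marked[, rev(seq_len(64))])
      dbl <- augment_pair(
        stick_image("f", cand$image$pixels, "mid"),
        cand$mask, flip_only, draw_seed = s)
      expect_identical(dbl$mask$values, marked)
      got_flip <- TRUE
      break
    }
  }
  expect_true(got_flip)

  # photometric-only policies never touch the mask
  photo <- augmentation_policy(rotations = numeric(0), horizontal_flip = FALSE)
  for (s in 1:10) {
    cand <- augment_pair(d$image, d$mask, photo, draw_seed = s)
    expect_identical(cand$mask$values, d$mask$values)
  }
})

test_that("small rotations lose little mask area on a smooth disk", {
  d <- disk_scene(256)
  r1 <- warp_rotate(d$mask$values, 10, "nearest", 0)
  r2 <- warp_rotate(r1, -10, "nearest", 0)
  expect_gte(mask_scores(r2, d$mask$values)$iou, 0.98)
})

test_that("dataset expansion yields n * (1 + variants) images", {
  set.seed(1)
  imgs <- lapply(1:3, function(i)
    stick_image(paste0("o", i), array(runif(8 * 8 * 3) * 255, c(8, 8, 3))))
  pol <- augmentation_policy(variants_per_original = 2)
  out <- expand_dataset(imgs, pol)
  expect_length(out, 9)
  expect_length(expand_dataset(imgs[[1]][integer(0)], pol), 0)
  one <- expand_dataset(imgs[1], pol)
  expect_length(one, 3)
  expect_equal(vapply(one, function(x) x$id, ""), c("o1", "o1_aug1", "o1_aug2"))
})

test_that("image and mask PNG round-trips preserve content", {
  d <- disk_scene(16)
  f1 <- tempfile(fileext = ".png")
  f2 <- tempfile(fileext = ".png")
  write_stick_image(d$image, f1)
  write_mask_png(d$mask, f2)
  img2 <- read_stick_image(f1, stage = "mid")
  expect_equal(img2$pixels, d$image$pixels, tolerance = 1 / 255)
  expect_identical(read_mask_png(f2)$values, d$mask$values)
})

test_that("augmentation policies load from YAML with a label map", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("rotations: [-10, 10]",
               "noise_fraction: 0.02",
               "variants_per_original: 3",
               "label_map:",
               "  '0': pre",
               "  '1': mid",
               "  '2': post"), f)
  pol <- read_augmentation_policy(f)
  expect_equal(pol$rotations, c(-10, 10))
  expect_equal(pol$noise_fraction, 0.02)
  expect_identical(pol$variants_per_original, 3L)
  expect_identical(unname(attr(pol, "label_map")["2"]), "post")
})
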