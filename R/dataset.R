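# Image / annotation I/O, polygon <-> mask conversion, dataset splitting and
# the augmentation policy used to expand the training corpus.

STAGES <- c("pre", "mid", "post")

#' Construct a stick image record
#'
#' @param id image identifier
#' @param pixels H x W x 3 numeric array, 8-bit scale (0..255)
#' @param stage maturity stage: "pre", "mid", "post" or "unknown"
#' @param background backdrop colour: "red", "green" or "unknown"
#' @param exposure_tag "low", "normal", "over" or "unknown"
#' @return an object of class `stick_image`
#' @export
stick_image <- function(id, pixels, stage = "unknown", background = "unknown",
                        exposure_tag = "unknown") {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            dim(pixels)[1] >= 1, dim(pixels)[2] >= 1)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  stage <- match.arg(stage, c(STAGES, "unknown"))
  structure(list(id = id, pixels = pixels, stage = stage,
                 background = match.arg(background, c("red", "green", "unknown")),
                 exposure_tag = match.arg(exposure_tag,
                                          c("low", "normal", "over", "unknown"))),
            class = "stick_image")
}

#' Construct a mask raster
#' @param image_id identifier of the paired image
#' @param values H x W matrix; 0/1 for binary masks, [0,1] for probabilities
#' @param kind "binary" or "probability"
#' @return an object of class `mask_raster`
#' @export
mask_raster <- function(image_id, values, kind = c("binary", "probability")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values))
  if (kind == "binary" && !all(values %in% c(0, 1)))
    stop("binary mask values must be 0 or 1")
  if (kind == "probability" && (min(values) < 0 || max(values) > 1))
    stop("probability mask values must lie in [0, 1]")
  structure(list(image_id = image_id, values = values, kind = kind),
            class = "mask_raster")
}

stage_from_label <- function(label, label_map = NULL) {
  if (is.null(label_map))
    label_map <- c("0" = "pre", "1" = "mid", "2" = "post",
                   "pre" = "pre", "mid" = "mid", "post" = "post")
  if (!label %in% names(label_map))
    stop("unknown label '", label, "'; permitted labels: ",
         paste(names(label_map), collapse = ", "))
  unname(label_map[label])
}

#' Parse a Labelme-style polygon annotation document
#'
#' Every polygon shape becomes one vertex sequence; the shape label string is
#' mapped to a maturity stage through `label_map` (defaults: "0" = pre,
#' "1" = mid, "2" = post).
#'
#' @param document JSON text, or a path to a JSON file
#' @param label_map named character vector mapping label strings to stages
#' @return an object of class `polygon_annotation` with fields `image_id`,
#'   `polygons` (list of n x 2 matrices, columns x = column and y = row,
#'   0-based) and `labels` (stage per polygon)
#' @export
parse_polygon_annotation <- function(document, label_map = NULL) {
  txt <- if (length(document) == 1 && !grepl("[{]", document) && file.exists(document))
    paste(readLines(document, warn = FALSE), collapse = "\n") else document
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) stop("malformed annotation JSON: ",
                                           conditionMessage(e)))
  shapes <- doc$shapes %||% list()
  polys <- list()
  labels <- character(0)
  for (si in seq_along(shapes)) {
    sh <- shapes[[si]]
    if (is.null(sh$points))
      stop("malformed annotation JSON: shape ", si, " lacks field 'points'")
    if (is.null(sh$label))
      stop("malformed annotation JSON: shape ", si, " lacks field 'label'")
    pts <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
    if (ncol(pts) != 2)
      stop("malformed annotation JSON: shape ", si, " field 'points' is not a list of (x, y) pairs")
    colnames(pts) <- c("x", "y")
    polys[[length(polys) + 1L]] <- pts
    labels <- c(labels, stage_from_label(as.character(sh$label), label_map))
  }
  structure(list(image_id = doc$imagePath %||% doc$image_id %||% "",
                 polygons = polys, labels = labels),
            class = "polygon_annotation")
}

#' Serialise polygons to a Labelme-style JSON document
#' @param annotation a `polygon_annotation`
#' @param path optional file to write
#' @return JSON text, invisibly when writing to a file
#' @export
write_labelme <- function(annotation, path = NULL) {
  inv_map <- c(pre = "0", mid = "1", post = "2")
  shapes <- lapply(seq_along(annotation$polygons), function(i) {
    pts <- annotation$polygons[[i]]
    list(label = unname(inv_map[annotation$labels[i]]),
         points = lapply(seq_len(nrow(pts)), function(r) c(pts[r, 1], pts[r, 2])),
         shape_type = "polygon")
  })
  txt <- jsonlite::toJSON(list(imagePath = annotation$image_id, shapes = shapes),
                          auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# Even-odd (ray-crossing) point-in-polygon test for a set of points.
points_in_polygon <- function(px, py, poly) {
  inside <- rep(FALSE, length(px))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterise polygon annotations to a binary mask
#'
#' A pixel is set iff its centre lies inside any polygon under the even-odd
#' rule (pixel-centre, 0-based, x = column / y = row convention); overlapping
#' polygons union.
#'
#' @param annotation a `polygon_annotation`
#' @param height,width output raster size
#' @return a binary `mask_raster`
#' @export
polygon_to_mask <- function(annotation, height, width) {
  stopifnot(height >= 1, width >= 1)
  vals <- matrix(0, height, width)
  px <- rep(seq_len(width) - 1, each = height)
  py <- rep(seq_len(height) - 1, times = width)
  for (poly in annotation$polygons) {
    if (nrow(poly) < 3) stop("polygon must have at least 3 vertices")
    inside <- points_in_polygon(px, py, poly)
    vals[inside] <- 1
  }
  mask_raster(annotation$image_id, vals, "binary")
}

#' Trace the contours of a binary mask back to polygons
#'
#' Extracts iso-0.5 contours of the mask; on solid shapes the polygons
#' rasterise back to the original mask.
#' @param mask a binary `mask_raster`
#' @param stage stage label to attach
#' @return a `polygon_annotation`
#' @export
mask_to_polygons <- function(mask, stage = "mid") {
  v <- mask$values
  H <- nrow(v); W <- ncol(v)
  # pad so contours of blobs touching the border close properly
  z <- matrix(0, H + 2, W + 2)
  z[2:(H + 1), 2:(W + 1)] <- v
  cl <- grDevices::contourLines(x = seq_len(H + 2) - 2, y = seq_len(W + 2) - 2,
                                z = z, levels = 0.5)
  polys <- lapply(cl, function(p) {
    m <- cbind(x = p$y, y = p$x)   # contourLines' x follows matrix rows
    m[-nrow(m), , drop = FALSE]
  })
  polys <- Filter(function(p) nrow(p) >= 3, polys)
  structure(list(image_id = mask$image_id, polygons = polys,
                 labels = rep(stage, length(polys))),
            class = "polygon_annotation")
}

#' Split image ids into train/validation/test sets
#'
#' Sizes follow round-half-up of `n * ratio` for the validation and test sets
#' with the remainder assigned to training; the shuffle is deterministic under
#' `seed`.
#' @param ids character vector of unique ids
#' @param ratios three nonnegative reals summing to 1 (train, val, test)
#' @param seed integer seed
#' @return list with `train_ids`, `val_ids`, `test_ids`, `ratios`, `seed`
#' @export
split_dataset <- function(ids, ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  if (anyDuplicated(ids)) stop("duplicate ids")
  if (length(ids) == 0) stop("ids must be non-empty")
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  n <- length(ids)
  round_half_up <- function(x) floor(x + 0.5)
  n_val <- round_half_up(n * ratios[2])
  n_test <- round_half_up(n * ratios[3])
  n_train <- n - n_val - n_test
  if (n_train < 0) stop("ratios leave no room for the training set")
  sh <- with_seed(seed, sample(ids))
  structure(list(train_ids = sh[seq_len(n_train)],
                 val_ids = sh[n_train + seq_len(n_val)],
                 test_ids = sh[n_train + n_val + seq_len(n_test)],
                 ratios = ratios, seed = seed),
            class = "split_assignment")
}

#' Augmentation policy
#'
#' Magnitude sets follow the corpus-expansion recipe: rotations of +-10 and
#' +-15 degrees, brightness/contrast scaling of +-3/5/7 percent, 1% additive
#' Gaussian noise, horizontal flips, +-8 percent exposure gain and +-3 percent
#' saturation scaling. Each enabled transform is included independently with
#' probability 0.5 per draw; magnitudes are drawn uniformly from their sets.
#'
#' @param rotations candidate rotation angles (degrees)
#' @param brightness_contrast candidate brightness/contrast percentages
#' @param noise_fraction additive Gaussian noise sigma as a fraction of full scale
#' @param horizontal_flip allow horizontal flips
#' @param exposure candidate exposure-gain percentages
#' @param saturation candidate saturation percentages
#' @param variants_per_original augmented copies per original in
#'   [expand_dataset()]
#' @param seed base seed for corpus expansion
#' @return an `augmentation_policy` object
#' @export
augmentation_policy <- function(rotations = c(-15, -10, 10, 15),
                                brightness_contrast = c(-7, -5, -3, 3, 5, 7),
                                noise_fraction = 0.01,
                                horizontal_flip = TRUE,
                                exposure = c(-8, 8),
                                saturation = c(-3, 3),
                                variants_per_original = 2L,
                                seed = 0L) {
  stopifnot(variants_per_original >= 0)
  structure(list(rotations = rotations,
                 brightness_contrast = brightness_contrast,
                 noise_fraction = noise_fraction,
                 horizontal_flip = horizontal_flip,
                 exposure = exposure, saturation = saturation,
                 variants_per_original = as.integer(variants_per_original),
                 seed = seed),
            class = "augmentation_policy")
}

median_border_color <- function(px) {
  H <- dim(px)[1]; W <- dim(px)[2]
  sel <- rbind(cbind(1, seq_len(W)), cbind(H, seq_len(W)),
               cbind(seq_len(H), 1), cbind(seq_len(H), W))
  vapply(1:3, function(c) stats::median(px[, , c][sel]), 0)
}

#' Apply a random combination of augmentations to an image/mask pair
#'
#' Geometric transforms (rotation, horizontal flip) are applied identically to
#' image and mask (nearest-neighbour mask resampling, frame preserved with the
#' median border colour as fill); photometric transforms (brightness/contrast,
#' exposure, saturation, noise) modify the image only. Deterministic under
#' `draw_seed`.
#'
#' @param image a `stick_image`
#' @param mask a binary `mask_raster` of matching size
#' @param policy an `augmentation_policy`
#' @param draw_seed integer seed for this draw
#' @return list with elements `image` and `mask`
#' @export
augment_pair <- function(image, mask, policy, draw_seed = 0L) {
  if (!all(dim(image$pixels)[1:2] == dim(mask$values)))
    stop("image and mask dimensions differ")
  with_seed(draw_seed, {
    px <- image$pixels
    mv <- mask$values
    pick <- function(set) set[sample.int(length(set), 1L)]
    on_ <- function(enabled) enabled && stats::runif(1) < 0.5
    if (on_(length(policy$rotations) > 0)) {
      ang <- pick(policy$rotations)
      fill <- median_border_color(px)
      px <- warp_rotate(px, ang, "bilinear", fill)
      mv <- warp_rotate(mv, ang, "nearest", 0)
    }
    if (on_(isTRUE(policy$horizontal_flip))) {
      px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
      mv <- mv[, rev(seq_len(ncol(mv))), drop = FALSE]
    }
    if (on_(length(policy$brightness_contrast) > 0)) {
      k <- pick(policy$brightness_contrast) / 100
      for (c in 1:3) {                 # scale about the channel mean
        mu <- mean(px[, , c])
        px[, , c] <- mu + (px[, , c] - mu) * (1 + k)
      }
    }
    if (on_(length(policy$exposure) > 0)) {
      px <- px * (1 + pick(policy$exposure) / 100)
    }
    if (on_(length(policy$saturation) > 0)) {
      hsv <- rgb2hsv_arr(clamp255(px))
      hsv[, , 2] <- pmin(pmax(hsv[, , 2] * (1 + pick(policy$saturation) / 100), 0), 1)
      px <- hsv2rgb_arr(hsv)
    }
    if (on_(policy$noise_fraction > 0)) {
      px <- px + stats::rnorm(length(px), 0, policy$noise_fraction * 255)
    }
    px <- clamp255(px)
    list(image = stick_image(image$id, px, image$stage, image$background,
                             image$exposure_tag),
         mask = mask_raster(mask$image_id, mv, mask$kind))
  })
}

#' Expand a dataset with augmented variants
#'
#' Returns the originals followed by `variants_per_original` augmented copies
#' of each, so the total count is `n * (1 + variants_per_original)`.
#' @param originals list of `stick_image` objects
#' @param policy an `augmentation_policy`
#' @param masks optional list of matching masks (all-zero masks assumed
#'   otherwise)
#' @return list of `stick_image` objects
#' @export
expand_dataset <- function(originals, policy, masks = NULL) {
  out <- list()
  for (i in seq_along(originals)) {
    im <- originals[[i]]
    out[[length(out) + 1L]] <- im
    mk <- if (is.null(masks)) {
      mask_raster(im$id, matrix(0, dim(im$pixels)[1], dim(im$pixels)[2]))
    } else masks[[i]]
    for (v in seq_len(policy$variants_per_original)) {
      draw <- policy$seed + (i - 1L) * policy$variants_per_original + v
      aug <- augment_pair(im, mk, policy, draw_seed = draw)
      aug$image$id <- paste0(im$id, "_aug", v)
      out[[length(out) + 1L]] <- aug$image
    }
  }
  out
}

# ---- on-disk formats -------------------------------------------------------

#' Read an RGB image (PNG or JPEG) as a stick image
#' @param path image file
#' @param id identifier (defaults to the file stem)
#' @param ... further fields passed to [stick_image()]
#' @return a `stick_image`
#' @export
read_stick_image <- function(path, id = tools::file_path_sans_ext(basename(path)),
                             ...) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    png::readPNG(path)
  } else {
    as.array(EBImage::readImage(path))
  }
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (ext != "png") px <- aperm(px, c(2, 1, 3))  # EBImage stores x,y
  stick_image(id, px[, , 1:3, drop = FALSE] * 255, ...)
}

#' Write a stick image as PNG
#' @param image a `stick_image`
#' @param path output file
#' @export
write_stick_image <- function(image, path) {
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Read a single-channel PNG as a mask (0/255 binary encoding)
#' @param path PNG file
#' @param image_id paired image id
#' @param kind "binary" or "probability"
#' @return a `mask_raster`
#' @export
read_mask_png <- function(path, image_id = tools::file_path_sans_ext(basename(path)),
                          kind = "binary") {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3) v <- v[, , 1]
  if (kind == "binary") v <- (v > 0.5) * 1
  mask_raster(image_id, v, kind)
}

#' Write a mask as a single-channel PNG (binary masks as 0/255)
#' @param mask a `mask_raster`
#' @param path output file
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask$values, path)
  invisible(path)
}

#' Write a split assignment as CSV (id, split)
#' @param split a `split_assignment`
#' @param path output file
#' @export
write_split_csv <- function(split, path) {
  df <- rbind(data.frame(id = split$train_ids, split = "train"),
              data.frame(id = split$val_ids, split = "val"),
              data.frame(id = split$test_ids, split = "test"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an augmentation policy (and optional label map) from YAML
#'
#' Keys mirror the arguments of [augmentation_policy()]; an optional
#' `label_map` block maps annotation label strings to stage names.
#' @param path YAML file
#' @return an `augmentation_policy`; any label map is attached as the
#'   `"label_map"` attribute
#' @export
read_augmentation_policy <- function(path) {
  y <- yaml::read_yaml(path)
  lm <- y$label_map
  y$label_map <- NULL
  pol <- do.call(augmentation_policy, lapply(y, unlist))
  if (!is.null(lm)) attr(pol, "label_map") <- unlist(lm)
  pol
}
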