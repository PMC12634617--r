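# Semi-automatic browning-region labelling: a random forest classifies every
# ROI pixel from the feature stack, trained on user scribbles.

#' Scribble set
#'
#' Sparse user-marked training pixels: browning (positive) and non-browning
#' (negative) coordinates, (row, col) 0-based.
#' @param image_id image identifier
#' @param positive_pixels,negative_pixels n x 2 matrices of (row, col)
#' @param provenance free-text note on how the scribbles were produced
#' @return a `scribble_set`
#' @export
scribble_set <- function(image_id, positive_pixels, negative_pixels,
                         provenance = "") {
  pos <- matrix(as.integer(positive_pixels), ncol = 2)
  neg <- matrix(as.integer(negative_pixels), ncol = 2)
  key <- function(m) paste(m[, 1], m[, 2])
  if (length(intersect(key(pos), key(neg))))
    stop("positive and negative scribbles overlap")
  if (nrow(pos) < 1 || nrow(neg) < 1)
    stop("each scribble class needs at least one pixel")
  structure(list(image_id = image_id, positive_pixels = pos,
                 negative_pixels = neg, provenance = provenance),
            class = "scribble_set")
}

#' Read / write scribbles as sidecar JSON
#' @param path JSON file
#' @return a `scribble_set`
#' @export
read_scribbles <- function(path) {
  d <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  scribble_set(d$image_id,
               matrix(unlist(d$positive_pixels), ncol = 2, byrow = is.list(d$positive_pixels)),
               matrix(unlist(d$negative_pixels), ncol = 2, byrow = is.list(d$negative_pixels)),
               d$provenance %||% "")
}

#' @rdname read_scribbles
#' @param scribbles a `scribble_set`
#' @export
write_scribbles <- function(scribbles, path) {
  jsonlite::write_json(list(image_id = scribbles$image_id,
                            positive_pixels = scribbles$positive_pixels,
                            negative_pixels = scribbles$negative_pixels,
                            provenance = scribbles$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

scribble_features <- function(stack, scribbles) {
  H <- dim(stack$features)[1]
  gather <- function(m) {
    idx <- m[, 2] * H + m[, 1] + 1    # (row, col) 0-based -> linear
    t(apply(m, 1, function(rc) stack$features[rc[1] + 1, rc[2] + 1, ]))
  }
  pos <- gather(scribbles$positive_pixels)
  neg <- gather(scribbles$negative_pixels)
  x <- rbind(pos, neg)
  colnames(x) <- stack$channel_names
  list(x = x, y = factor(c(rep(1, nrow(pos)), rep(0, nrow(neg))),
                         levels = c(0, 1)))
}

#' Fit the pixel-level random-forest classifier from scribbles
#'
#' @param stack a `pixel_feature_stack`
#' @param scribbles a `scribble_set`; all coordinates must fall inside the ROI
#' @param n_trees forest size
#' @param seed RNG seed (the fit is deterministic under it)
#' @return a `pixel_classifier` with the trained forest, the recipe hash the
#'   stack was built under, and the training accuracy on the scribbles
#' @export
fit_pixel_classifier <- function(stack, scribbles, n_trees = 100L, seed = 0L) {
  H <- dim(stack$features)[1]; W <- dim(stack$features)[2]
  all_px <- rbind(scribbles$positive_pixels, scribbles$negative_pixels)
  if (any(all_px[, 1] < 0 | all_px[, 1] >= H | all_px[, 2] < 0 | all_px[, 2] >= W))
    stop("scribble coordinates outside the image")
  inroi <- stack$roi[all_px[, 2] * H + all_px[, 1] + 1] > 0
  if (!all(inroi)) stop("scribble pixels must lie inside the ROI")
  tr <- scribble_features(stack, scribbles)
  if (length(unique(tr$y)) < 2) stop("scribbles cover a single class")
  fit <- with_seed(seed, randomForest::randomForest(
    x = tr$x, y = tr$y, ntree = n_trees,
    mtry = max(1L, floor(sqrt(ncol(tr$x))))))
  acc <- mean(stats::predict(fit, tr$x) == tr$y)
  structure(list(forest = fit, n_trees = n_trees,
                 recipe_hash = stack$recipe_hash,
                 class_map = c(`0` = "non-browning", `1` = "browning"),
                 train_accuracy = acc, seed = seed),
            class = "pixel_classifier")
}

#' Predict browning labels for every ROI pixel
#'
#' Applies the forest to each pixel of the feature stack, forces pixels
#' outside the ROI to zero and removes connected components smaller than
#' `min_component_px`.
#' @param classifier a `pixel_classifier`
#' @param stack a `pixel_feature_stack` built under the classifier's recipe
#' @param roi_mask binary `mask_raster` (defaults to the stack's ROI)
#' @param min_component_px components below this pixel count are dropped
#' @return a binary `mask_raster` of browning labels
#' @export
predict_browning_labels <- function(classifier, stack, roi_mask = NULL,
                                    min_component_px = 20L) {
  if (!identical(classifier$recipe_hash, stack$recipe_hash))
    stop("feature stack was built under a different recipe than the classifier")
  H <- dim(stack$features)[1]; W <- dim(stack$features)[2]
  roi <- if (is.null(roi_mask)) stack$roi else roi_mask$values
  sel <- which(roi > 0)
  out <- matrix(0, H, W)
  if (length(sel)) {
    xm <- matrix(stack$features, H * W, dim(stack$features)[3])
    colnames(xm) <- stack$channel_names
    pred <- stats::predict(classifier$forest, xm[sel, , drop = FALSE])
    out[sel] <- as.numeric(as.character(pred))
  }
  if (min_component_px > 0 && any(out > 0)) {
    lab <- EBImage::bwlabel(t(out))       # EBImage uses x,y order
    sizes <- table(lab[lab > 0])
    drop <- as.integer(names(sizes)[sizes < min_component_px])
    if (length(drop)) out[t(matrix(lab %in% drop, nrow(lab)))] <- 0
  }
  mask_raster(stack$image_id, out, "binary")
}

#' Persist / load a pixel classifier
#' @param classifier a `pixel_classifier`
#' @param path RDS file
#' @export
save_pixel_classifier <- function(classifier, path) {
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_pixel_classifier
#' @export
load_pixel_classifier <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "pixel_classifier"))
  obj
}
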