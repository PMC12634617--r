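# Per-pixel feature stack for the semi-automatic browning annotation engine:
# colour channels, difference-of-Gaussians band-pass responses, local
# histogram entropy, rotated line-kernel (membrane) projections and
# neighbourhood statistics.

#' Difference-of-Gaussians filter
#'
#' `G(sigma1) * x - G(sigma2) * x` with reflective boundary handling;
#' annihilates constants and acts as a band-pass edge enhancer.
#' @param image_channel numeric matrix
#' @param sigma1,sigma2 positive Gaussian scales
#' @return filtered matrix
#' @export
dog_filter <- function(image_channel, sigma1, sigma2) {
  if (sigma1 <= 0 || sigma2 <= 0) stop("sigma values must be positive")
  gaussian_blur(image_channel, sigma1) - gaussian_blur(image_channel, sigma2)
}

#' Shannon entropy of a histogram, in bits
#'
#' `-sum(p * log2(p))` over the nonzero entries after normalisation; the
#' primitive behind [local_entropy()]. Equal-count two-bin histograms score
#' exactly 1 bit, four equal bins exactly 2 bits.
#' @param counts nonnegative histogram counts (or probabilities)
#' @return entropy in bits
#' @export
shannon_entropy_bits <- function(counts) {
  stopifnot(all(counts >= 0))
  s <- sum(counts)
  if (s == 0) return(0)
  p <- counts[counts > 0] / s
  -sum(p * log2(p))
}

#' Local Shannon entropy
#'
#' Per-pixel entropy (bits) of the gray-value histogram over the
#' (2 radius + 1)^2 neighbourhood, with values binned into `n_bins` equal
#' intervals of the 0..255 range. Bounded by log2(min(n_bins, neighbourhood
#' size)).
#' @param image_channel numeric matrix on a 0..255 scale
#' @param radius neighbourhood radius (>= 1)
#' @param n_bins histogram bin count (>= 2)
#' @return entropy matrix
#' @export
local_entropy <- function(image_channel, radius = 4L, n_bins = 64L) {
  stopifnot(radius >= 1, n_bins >= 2)
  b <- pmin(floor(image_channel / 256 * n_bins), n_bins - 1)
  m <- (2 * radius + 1)^2
  H <- matrix(0, nrow(b), ncol(b))
  for (bin in unique(as.vector(b))) {
    cnt <- box_counts((b == bin) * 1, radius)
    p <- cnt / m
    term <- p * log2(p)
    term[p == 0] <- 0
    H <- H - term
  }
  H
}

membrane_kernel <- function(k, angle_deg) {
  # line of width 1 through the kernel centre at the given angle
  ctr <- (k + 1) / 2
  th <- angle_deg * pi / 180
  dx <- sin(th); dy <- cos(th)         # 0 degrees = vertical line
  kern <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    # distance from cell centre to the line through (ctr, ctr) along (dy, dx)
    px <- j - ctr; py <- i - ctr
    dist <- abs(px * dy - py * dx)
    if (dist <= 0.5) kern[i, j] <- 1
  }
  # normalise so every rotation responds identically to constants (the cell
  # count of a rasterised line varies with angle)
  kern / sum(kern)
}

#' Membrane projections
#'
#' Convolves the channel with a central-line kernel rotated through evenly
#' spaced angles and reduces the rotation stack with the named projections.
#' @param image_channel numeric matrix
#' @param kernel_size odd line-kernel size
#' @param rotations number of evenly spaced rotations over 180 degrees
#' @param projections subset of c("sum", "mean", "max", "min", "median", "std")
#' @return H x W x P array, one channel per projection
#' @export
membrane_projections <- function(image_channel, kernel_size = 19L,
                                 rotations = 6L,
                                 projections = c("sum", "mean", "max", "min",
                                                 "median", "std")) {
  if (kernel_size %% 2 == 0) stop("kernel size must be odd")
  projections <- match.arg(projections, several.ok = TRUE)
  angles <- seq(0, 180, length.out = rotations + 1)[seq_len(rotations)]
  H <- nrow(image_channel); W <- ncol(image_channel)
  stack <- array(0, c(H, W, rotations))
  for (a in seq_along(angles)) {
    stack[, , a] <- conv2d_same(image_channel, membrane_kernel(kernel_size, angles[a]))
  }
  sm <- matrix(stack, H * W, rotations)
  out <- array(0, c(H, W, length(projections)))
  for (p in seq_along(projections)) {
    v <- switch(projections[p],
      sum = rowSums(sm),
      mean = rowMeans(sm),
      max = do.call(pmax, asplit(sm, 2)),
      min = do.call(pmin, asplit(sm, 2)),
      median = apply(sm, 1, stats::median),
      std = sqrt(pmax(rowMeans(sm^2) - rowMeans(sm)^2, 0)))
    out[, , p] <- v
  }
  dimnames(out) <- list(NULL, NULL, paste0("membrane_", projections))
  out
}

#' Feature recipe for the pixel classifier
#'
#' Defaults follow common trainable-segmentation conventions: three DoG scale
#' pairs, entropy over a radius-4 window with 64 bins, a 19-pixel membrane
#' kernel with 6 rotations and all 6 projections, radius-2 neighbourhood
#' mean/std, and both RGB and HSV colour spaces.
#' @param dog_sigma_pairs list of (sigma1, sigma2) pairs with sigma1 < sigma2
#' @param entropy_radius,entropy_bins local-entropy window radius and bins
#' @param membrane_kernel_size,membrane_rotations,membrane_projections
#'   membrane-projection settings
#' @param neighborhood_radius radius for the local mean/std features
#' @param color_spaces subset of c("RGB", "HSV")
#' @return a `feature_recipe`
#' @export
feature_recipe <- function(dog_sigma_pairs = list(c(1, 2), c(2, 4), c(4, 8)),
                           entropy_radius = 4L, entropy_bins = 64L,
                           membrane_kernel_size = 19L, membrane_rotations = 6L,
                           membrane_projections = c("sum", "mean", "max",
                                                    "min", "median", "std"),
                           neighborhood_radius = 2L,
                           color_spaces = c("RGB", "HSV")) {
  for (p in dog_sigma_pairs)
    if (length(p) != 2 || p[1] <= 0 || p[2] <= 0 || p[1] >= p[2])
      stop("each DoG pair must be (sigma1, sigma2) with 0 < sigma1 < sigma2")
  stopifnot(entropy_radius >= 1, membrane_kernel_size %% 2 == 1,
            membrane_rotations >= 1, neighborhood_radius >= 1,
            all(color_spaces %in% c("RGB", "HSV")))
  r <- structure(list(dog_sigma_pairs = dog_sigma_pairs,
                      entropy_radius = as.integer(entropy_radius),
                      entropy_bins = as.integer(entropy_bins),
                      membrane_kernel_size = as.integer(membrane_kernel_size),
                      membrane_rotations = as.integer(membrane_rotations),
                      membrane_projections = membrane_projections,
                      neighborhood_radius = as.integer(neighborhood_radius),
                      color_spaces = color_spaces),
                 class = "feature_recipe")
  r
}

recipe_hash <- function(recipe) {
  f <- tempfile()
  writeLines(as.character(jsonlite::toJSON(unclass(recipe), auto_unbox = TRUE,
                                           digits = NA)), f)
  h <- unname(tools::md5sum(f))
  unlink(f)
  h
}

#' Build the per-pixel feature stack
#'
#' Concatenates, in order: raw RGB; HSV; one DoG response per scale pair (on
#' luminance); local entropy; membrane projections; and neighbourhood mean
#' and standard deviation of luminance. Pixels outside the ROI carry features
#' but are flagged for exclusion via the attached ROI mask.
#' @param image a `stick_image` (usually an ROI crop)
#' @param roi_mask binary `mask_raster` aligned with the image
#' @param recipe a `feature_recipe`
#' @return a `pixel_feature_stack`: list with `features` (H x W x F),
#'   `channel_names`, `roi`, `recipe_hash`
#' @export
build_feature_stack <- function(image, roi_mask, recipe = feature_recipe()) {
  if (!inherits(recipe, "feature_recipe")) stop("invalid recipe")
  px <- image$pixels
  if (!all(dim(px)[1:2] == dim(roi_mask$values)))
    stop("image and ROI mask are not aligned")
  H <- dim(px)[1]; W <- dim(px)[2]
  chans <- list()
  if ("RGB" %in% recipe$color_spaces) {
    chans$red <- px[, , 1]; chans$green <- px[, , 2]; chans$blue <- px[, , 3]
  }
  if ("HSV" %in% recipe$color_spaces) {
    hsv <- rgb2hsv_arr(px)
    chans$hue <- hsv[, , 1] * 255
    chans$saturation <- hsv[, , 2] * 255
    chans$value <- hsv[, , 3] * 255
  }
  lum <- luminance(px)
  for (p in recipe$dog_sigma_pairs) {
    chans[[sprintf("dog_%g_%g", p[1], p[2])]] <- dog_filter(lum, p[1], p[2])
  }
  chans$entropy <- local_entropy(lum, recipe$entropy_radius, recipe$entropy_bins)
  mp <- membrane_projections(lum, recipe$membrane_kernel_size,
                             recipe$membrane_rotations,
                             recipe$membrane_projections)
  for (p in seq_len(dim(mp)[3])) chans[[dimnames(mp)[[3]][p]]] <- mp[, , p]
  r <- recipe$neighborhood_radius
  m <- (2 * r + 1)^2
  nmean <- box_counts(lum, r) / m
  nsq <- box_counts(lum^2, r) / m
  chans$neigh_mean <- nmean
  chans$neigh_std <- sqrt(pmax(nsq - nmean^2, 0))
  F <- length(chans)
  feats <- array(0, c(H, W, F))
  for (i in seq_len(F)) feats[, , i] <- chans[[i]]
  if (any(!is.finite(feats))) stop("non-finite feature values")
  structure(list(image_id = image$id, features = feats,
                 channel_names = names(chans), roi = roi_mask$values,
                 recipe_hash = recipe_hash(recipe)),
            class = "pixel_feature_stack")
}
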