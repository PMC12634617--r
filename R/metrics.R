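# Evaluation metrics, browning-ratio quantification, pigmentation heatmaps
# and model-complexity audits.

box_iou <- function(a, b) {
  # boxes are (x1, y1, x2, y2)
  ix <- pmax(0, pmin(a[3], b[3]) - pmax(a[1], b[1]))
  iy <- pmax(0, pmin(a[4], b[4]) - pmax(a[2], b[2]))
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) return(0)
  inter / ua
}

match_boxes <- function(predictions, truths, iou_threshold = 0.5,
                        method = c("greedy", "hungarian")) {
  method <- match.arg(method)
  np <- length(predictions); nt <- length(truths)
  if (np == 0 || nt == 0)
    return(list(tp = 0L, fp = np, fn = nt))
  conf <- vapply(predictions, function(p) p$confidence %||% 1, 0)
  iou <- matrix(0, np, nt)
  for (i in seq_len(np)) for (j in seq_len(nt))
    iou[i, j] <- box_iou(predictions[[i]]$box, truths[[j]]$box)
  if (method == "greedy") {
    used <- rep(FALSE, nt)
    tp <- 0L
    for (i in order(conf, decreasing = TRUE)) {
      cand <- which(!used & iou[i, ] >= iou_threshold)
      if (length(cand)) {
        j <- cand[which.max(iou[i, cand])]
        used[j] <- TRUE
        tp <- tp + 1L
      }
    }
  } else {
    # exhaustive optimal one-to-one matching (small instance counts)
    best <- 0L
    perms <- function(v) if (length(v) <= 1) list(v) else
      unlist(lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
    ords <- perms(seq_len(min(np, 8L)))
    for (ord in ords) {
      used <- rep(FALSE, nt)
      tp <- 0L
      for (i in ord) {
        cand <- which(!used & iou[i, ] >= iou_threshold)
        if (length(cand)) {
          j <- cand[which.max(iou[i, cand])]
          used[j] <- TRUE
          tp <- tp + 1L
        }
      }
      best <- max(best, tp)
    }
    tp <- best
  }
  list(tp = tp, fp = np - tp, fn = nt - tp)
}

#' Box-level detection precision
#'
#' Predictions are matched one-to-one to ground-truth boxes greedily in order
#' of descending confidence; a prediction is a true positive iff its best
#' unmatched truth overlaps with IoU at or above the threshold. Returns
#' TP / (TP + FP); with no predictions the precision is vacuously 1 (the
#' corresponding recall is 0).
#'
#' @param predictions list of records with `$box` = (x1, y1, x2, y2) and
#'   `$confidence`
#' @param truths list of records with `$box`
#' @param iou_threshold matching threshold (default 0.5)
#' @param method "greedy" (default) or "hungarian" exhaustive matching
#' @return precision in [0, 1]
#' @export
box_precision <- function(predictions, truths, iou_threshold = 0.5,
                          method = "greedy") {
  m <- match_boxes(predictions, truths, iou_threshold, method)
  if (m$tp + m$fp == 0) return(1)
  m$tp / (m$tp + m$fp)
}

#' Box-level detection recall
#' @inheritParams box_precision
#' @return recall in [0, 1]; vacuously 1 with no ground truths
#' @export
box_recall <- function(predictions, truths, iou_threshold = 0.5,
                       method = "greedy") {
  m <- match_boxes(predictions, truths, iou_threshold, method)
  if (m$tp + m$fn == 0) return(1)
  m$tp / (m$tp + m$fn)
}

#' Pixel-level mask scores
#'
#' Set-operation scores between a predicted and a ground-truth binary mask:
#' precision |P&G|/|P|, recall |P&G|/|G|, their harmonic-mean F1, and IoU
#' |P&G|/|P|G|. Empty denominators follow explicit conventions: an empty
#' prediction scores precision 1 against an empty truth and 0 otherwise
#' (mirrored for recall); the IoU of two empty masks is 1.
#'
#' @param P,G binary `mask_raster` objects (or plain 0/1 matrices) of equal
#'   size
#' @return list with `precision`, `recall`, `f1`, `iou`
#' @export
mask_scores <- function(P, G) {
  pv <- if (inherits(P, "mask_raster")) P$values else P
  gv <- if (inherits(G, "mask_raster")) G$values else G
  if (!all(dim(pv) == dim(gv))) stop("mask shapes differ")
  p <- sum(pv)
  g <- sum(gv)
  i <- sum(pv * gv)
  u <- p + g - i
  precision <- if (p == 0) as.numeric(g == 0) else i / p
  recall <- if (g == 0) as.numeric(p == 0) else i / g
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  iou <- if (u == 0) 1 else i / u
  list(precision = precision, recall = recall, f1 = f1, iou = iou)
}

#' Mean intersection-over-union across classes
#' @param per_class_ious numeric vector of per-class IoU values in [0, 1]
#' @return their arithmetic mean
#' @export
mean_iou <- function(per_class_ious) {
  if (length(per_class_ious) == 0) stop("empty IoU list")
  stopifnot(all(per_class_ious >= 0 & per_class_ious <= 1))
  mean(per_class_ious)
}

#' Browning area ratio within a stick ROI
#'
#' Browning pixels outside the ROI are clipped before counting; the ratio is
#' reported in percent of the ROI area.
#' @param browning_mask binary `mask_raster` of browning pixels
#' @param roi_mask binary `mask_raster` of the stick region
#' @return list with `roi_pixels`, `browning_pixels`, `ratio_percent`
#' @export
browning_ratio <- function(browning_mask, roi_mask) {
  bv <- if (inherits(browning_mask, "mask_raster")) browning_mask$values else browning_mask
  rv <- if (inherits(roi_mask, "mask_raster")) roi_mask$values else roi_mask
  if (!all(dim(bv) == dim(rv))) stop("mask shapes differ")
  roi_px <- sum(rv)
  if (roi_px == 0) stop("no stick region")
  br <- sum(bv * rv)
  list(roi_pixels = as.integer(roi_px), browning_pixels = as.integer(br),
       ratio_percent = 100 * br / roi_px)
}

#' Pigmentation-intensity heatmap
#'
#' Pigment intensity is one minus the normalised luminance, restricted to the
#' browning region and min-max normalised within it (a zero-range region maps
#' to 0.5). This is a reconstruction for visualisation, not a colorimetric
#' measurement.
#' @param image_roi a `stick_image` (ROI crop)
#' @param browning_mask binary `mask_raster` aligned with the crop
#' @return H x W matrix in [0, 1], nonzero only inside the browning mask
#' @export
pigment_heatmap <- function(image_roi, browning_mask) {
  bv <- if (inherits(browning_mask, "mask_raster")) browning_mask$values else browning_mask
  if (!all(dim(image_roi$pixels)[1:2] == dim(bv))) stop("shapes differ")
  if (sum(bv) == 0) {
    warning("empty browning mask; returning an all-zero heatmap")
    return(matrix(0, nrow(bv), ncol(bv)))
  }
  lum <- luminance(image_roi$pixels) / 255
  intens <- 1 - lum
  sel <- bv > 0
  rng <- range(intens[sel])
  out <- matrix(0, nrow(bv), ncol(bv))
  out[sel] <- if (diff(rng) == 0) 0.5 else (intens[sel] - rng[1]) / diff(rng)
  out
}

#' Model-complexity audit
#'
#' Reports the trainable-parameter count, per-forward-pass convolution FLOPs
#' at a stated input resolution under both the multiply-accumulate (MAC) and
#' the two-operation counting conventions, and the on-disk size of a
#' serialised checkpoint.
#' @param model a module tree carrying a shape trace (see
#'   [assemble_contour_model()] / [assemble_rsunet()])
#' @param input_size spatial input resolution c(H, W)
#' @return list with `params`, `flops_mac`, `flops_2x`, `serialized_size_mb`
#' @export
complexity_audit <- function(model, input_size = c(640, 640)) {
  params <- count_parameters(model)
  macs <- if (!is.null(model$meta$count_macs)) {
    model$meta$count_macs(input_size)
  } else {
    # generic sequential walk (networks assembled by the package carry an
    # exact trace instead, since skip/upsample topologies are not sequential)
    walk <- function(x, s) {
      if (x$kind == "conv_bn") {
        s <- s / (x$meta$stride^2)
        macs_acc <<- macs_acc + x$meta$cout * (x$meta$cin / x$meta$groups) *
          x$meta$k^2 * input_size[1] * input_size[2] * s
        return(s)
      }
      for (ch in x$children) s <- walk(ch, s)
      s
    }
    macs_acc <- 0
    walk(model, 1)
    macs_acc
  }
  f <- tempfile(fileext = ".rds")
  saveRDS(save_checkpoint_obj(model), f)
  sz <- file.size(f) / 2^20
  unlink(f)
  list(params = params, flops_mac = macs, flops_2x = 2 * macs,
       serialized_size_mb = sz)
}
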