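# Stage-1 contour network: a lightweight anchor-free single-stage instance
# segmenter in the YOLO v11-seg mould.  The backbone is built from
# VanillaNet-style grouped-convolution blocks (widths 16/32/48/96/160 at full
# scale, one downsampling block plus two repeat blocks per stage); the PAN
# neck uses plain 3x3 convolutions; decoupled box/class branches (hidden
# width c/2) and a 16-prototype mask head sit on the three finest pyramid
# levels.  With the Ghost segmentation head and no SPPF block (the VG
# configuration) the full-scale model holds 1,519,513 parameters (1.5 M);
# with a standard head it holds 1,700,413 (1.7 M).

CONTOUR_BASE_WIDTHS <- c(16L, 32L, 48L, 96L, 160L)

#' Stage-1 contour model configuration
#'
#' @param width_multiplier scales all channel counts (1 = full scale)
#' @param num_classes number of maturity stages (3)
#' @param mask_prototype_count prototype masks shared across instances
#' @param input_size c(H, W) network input (letterboxed)
#' @param ghost_head replace the 3x3 convolutions of the box/class branches
#'   and prototype head with GhostConv (ratio 2, cheap kernel 3)
#' @param use_sppf keep a spatial-pyramid-pooling block on the deepest level
#' @param activation backbone block activation ("dynamic_relu" or "relu")
#' @param stage_repeats repeat blocks per backbone stage
#' @return a `contour_model_config`
#' @export
contour_model_config <- function(width_multiplier = 1, num_classes = 3L,
                                 mask_prototype_count = 16L,
                                 input_size = c(640L, 640L),
                                 ghost_head = TRUE, use_sppf = FALSE,
                                 activation = "dynamic_relu",
                                 stage_repeats = 2L) {
  stopifnot(width_multiplier > 0, num_classes == 3L,
            mask_prototype_count >= 1, all(input_size %% 32 == 0))
  structure(list(width_multiplier = width_multiplier,
                 num_classes = as.integer(num_classes),
                 mask_prototype_count = as.integer(mask_prototype_count),
                 input_size = as.integer(input_size),
                 ghost_head = isTRUE(ghost_head), use_sppf = isTRUE(use_sppf),
                 activation = activation,
                 stage_repeats = as.integer(stage_repeats)),
            class = "contour_model_config")
}

sc_width4 <- function(x, m) pmax(4L, 4L * as.integer(round(x * m / 4)))

# 3x3 stride-1 max pooling with same padding (used by SPPF).
op_maxpool3_same <- function(tp, xid) {
  force(xid)
  x <- tp$vals[[xid]]
  d <- dim(x)
  H <- d[1]; W <- d[2]
  xp <- array(-Inf, c(H + 2, W + 2, d[3], d[4]))
  xp[2:(H + 1), 2:(W + 1), , ] <- x
  y <- array(-Inf, d)
  arg <- array(0L, d)
  s <- 0L
  for (dj in 0:2) for (di in 0:2) {
    s <- s + 1L
    cand <- xp[di + seq_len(H), dj + seq_len(W), , , drop = FALSE]
    upd <- cand > y
    y[upd] <- cand[upd]
    arg[upd] <- s
  }
  tp_push(tp, y, xid, function(grad) {
    gp <- array(0, c(H + 2, W + 2, d[3], d[4]))
    s <- 0L
    for (dj in 0:2) for (di in 0:2) {
      s <- s + 1L
      sel <- arg == s
      g <- array(0, d)
      g[sel] <- grad[sel]
      gp[di + seq_len(H), dj + seq_len(W), , ] <-
        gp[di + seq_len(H), dj + seq_len(W), , ] + g
    }
    list(gp[2:(H + 1), 2:(W + 1), , , drop = FALSE])
  })
}

#' Assemble the stage-1 contour model
#'
#' Builds the backbone, neck and heads per the configuration and returns a
#' module tree exposing its trainable-parameter count and a MAC trace.
#' @param config a [contour_model_config()]
#' @return a module; `$fwd` maps (H, W, 3, N) input to a named list of
#'   per-scale raw head outputs plus mask prototypes
#' @export
assemble_contour_model <- function(config = contour_model_config()) {
  stopifnot(inherits(config, "contour_model_config"))
  mlt <- config$width_multiplier
  w <- sc_width4(CONTOUR_BASE_WIDTHS, mlt)
  act <- config$activation
  np <- config$mask_prototype_count
  nc <- config$num_classes
  trace <- list()
  tr <- function(mod, scale) {
    walk <- function(x, s) {
      if (x$kind == "conv_bn") {
        s_out <- s / (x$meta$stride^2)
        trace[[length(trace) + 1L]] <<-
          list(cin = x$meta$cin, cout = x$meta$cout, k = x$meta$k,
               groups = x$meta$groups, scale = s_out)
        return(s_out)
      }
      if (x$kind == "vanilla_block") {
        s <- walk(x$children[[1]], s)
        if (isTRUE(x$meta$downsample)) s <- s / 4
        return(s)
      }
      for (ch in x$children) s <- walk(ch, s)
      s
    }
    walk(mod, scale)
    mod
  }

  stem <- tr(conv_bn(3L, w[1], k = 3L, stride = 2L), 1)
  stage <- function(cin, cout, scale) {
    mods <- list(build_vanilla_block(cin, cout, downsample = TRUE,
                                     activation = act))
    for (i in seq_len(config$stage_repeats))
      mods <- c(mods, list(build_vanilla_block(cout, cout, activation = act)))
    tr(sequential_module("stage", mods), scale)
  }
  st1 <- stage(w[1], w[2], 1 / 4)      # -> 1/4
  st2 <- stage(w[2], w[3], 1 / 16)     # -> 1/8  (P3)
  st3 <- stage(w[3], w[4], 1 / 64)     # -> 1/16 (P4)
  st4 <- stage(w[4], w[5], 1 / 256)    # -> 1/32 (P5)

  sppf <- if (config$use_sppf) {
    cv1 <- conv_bn(w[5], w[5] %/% 2L, k = 1L)
    cv2 <- conv_bn(2L * w[5], w[5], k = 1L)
    tr(cv1, 1 / 1024); tr(cv2, 1 / 1024)
    mm <- new_module("sppf", children = list(cv1, cv2))
    mm$fwd <- function(tp, xid, training = TRUE) {
      a <- cv1$fwd(tp, xid, training)
      b <- op_maxpool3_same(tp, a)
      cc <- op_maxpool3_same(tp, b)
      dd <- op_maxpool3_same(tp, cc)
      cv2$fwd(tp, op_concat_c(tp, list(a, b, cc, dd)), training)
    }
    mm
  } else NULL

  # neck: top-down then bottom-up (plain 3x3 convolutions)
  n4c <- tr(conv_bn(w[5] + w[4], w[4], k = 3L), 1 / 256)
  n3c <- tr(conv_bn(w[4] + w[3], w[3], k = 3L), 1 / 64)
  d3c <- tr(conv_bn(w[3], w[3], k = 3L, stride = 2L), 1 / 64)
  m4c <- tr(conv_bn(w[3] + w[4], w[4], k = 3L), 1 / 256)
  d4c <- tr(conv_bn(w[4], w[4], k = 3L, stride = 2L), 1 / 256)
  m5c <- tr(conv_bn(w[4] + w[5], w[5], k = 3L), 1 / 1024)

  head_conv <- function(cin, cout) {
    if (config$ghost_head)
      build_ghost_conv(cin, cout, primary_kernel = 3L, ratio = 2L,
                       cheap_kernel = 3L)
    else conv_bn(cin, cout, k = 3L)
  }
  scales <- c(8L, 16L, 32L)
  head_c <- c(w[3], w[4], w[5])
  heads <- lapply(1:3, function(i) {
    c_in <- head_c[i]
    hc <- max(16L, c_in %/% 2L)
    h <- list(box_conv = head_conv(c_in, hc),
              box_out = conv_bn(hc, 4L, k = 1L, bias = TRUE, bn = FALSE, act = "none"),
              cls_conv = head_conv(c_in, hc),
              cls_out = conv_bn(hc, nc, k = 1L, bias = TRUE, bn = FALSE, act = "none"),
              coef_out = conv_bn(c_in, np, k = 1L, bias = TRUE, bn = FALSE, act = "none"))
    for (mm in h) tr(mm, 1 / scales[i]^2)
    h
  })
  proto1 <- head_conv(w[3], w[3])
  proto2 <- head_conv(w[3], w[3] %/% 2L)
  proto3 <- conv_bn(w[3] %/% 2L, np, k = 1L, bias = TRUE, bn = FALSE, act = "none")
  tr(proto1, 1 / 64); tr(proto2, 1 / 16); tr(proto3, 1 / 16)

  kids <- Filter(Negate(is.null), c(
    list(stem, st1, st2, st3, st4, sppf, n4c, n3c, d3c, m4c, d4c, m5c,
         proto1, proto2, proto3),
    unlist(heads, recursive = FALSE)))
  model <- new_module("contour_model", children = kids,
                      meta = list(config = config, strides = scales))
  model$meta$count_macs <- function(input_size) {
    sum(vapply(trace, function(t)
      t$cout * (t$cin / t$groups) * t$k^2 *
        input_size[1] * input_size[2] * t$scale, 0))
  }
  model$fwd <- function(tp, xid, training = TRUE) {
    x <- stem$fwd(tp, xid, training)
    x <- st1$fwd(tp, x, training)
    p3 <- st2$fwd(tp, x, training)
    p4 <- st3$fwd(tp, p3, training)
    p5 <- st4$fwd(tp, p4, training)
    if (!is.null(sppf)) p5 <- sppf$fwd(tp, p5, training)
    n4 <- n4c$fwd(tp, op_concat_c(tp, list(op_upsample2(tp, p5, "nearest"), p4)), training)
    n3 <- n3c$fwd(tp, op_concat_c(tp, list(op_upsample2(tp, n4, "nearest"), p3)), training)
    m4 <- m4c$fwd(tp, op_concat_c(tp, list(d3c$fwd(tp, n3, training), n4)), training)
    m5 <- m5c$fwd(tp, op_concat_c(tp, list(d4c$fwd(tp, m4, training), p5)), training)
    feats <- list(n3, m4, m5)
    outs <- lapply(1:3, function(i) {
      h <- heads[[i]]
      list(box = h$box_out$fwd(tp, h$box_conv$fwd(tp, feats[[i]], training), training),
           cls = h$cls_out$fwd(tp, h$cls_conv$fwd(tp, feats[[i]], training), training),
           coef = h$coef_out$fwd(tp, feats[[i]], training))
    })
    protos <- proto3$fwd(tp,
      proto2$fwd(tp, op_upsample2(tp, proto1$fwd(tp, n3, training), "nearest"),
                 training), training)   # 1/4 resolution
    list(scales = outs, protos = protos)
  }
  model
}

# ---- pre/post-processing ---------------------------------------------------

#' Letterbox-resize an image to a target size
#'
#' Aspect-preserving bilinear resize padded with a neutral grey; returns the
#' mapping needed to project predictions back.
#' @param px H x W x 3 array (0..255)
#' @param target c(H, W) target size
#' @param fill pad value
#' @return list(img, scale, pad = c(top, left), src = c(H, W))
#' @export
letterbox_resize <- function(px, target, fill = 114) {
  H <- dim(px)[1]; W <- dim(px)[2]
  s <- min(target[1] / H, target[2] / W)
  nh <- max(1L, round(H * s)); nw <- max(1L, round(W * s))
  rs <- resize_img(px, nh, nw, "bilinear")
  out <- array(fill, c(target[1], target[2], dim(px)[3]))
  top <- (target[1] - nh) %/% 2L
  left <- (target[2] - nw) %/% 2L
  out[top + seq_len(nh), left + seq_len(nw), ] <- rs
  list(img = out, scale = s, pad = c(top, left), src = c(H, W))
}

decode_outputs <- function(model, raw, tp) {
  strides <- model$meta$strides
  np <- model$meta$config$mask_prototype_count
  rows <- list()
  for (i in seq_along(raw$scales)) {
    sc <- raw$scales[[i]]
    bx <- tp_val(tp, sc$box); cl <- tp_val(tp, sc$cls); cf <- tp_val(tp, sc$coef)
    d <- dim(bx)
    st <- strides[i]
    cy <- (rep(seq_len(d[1]) - 1, times = d[2]) + 0.5) * st
    cx <- (rep(seq_len(d[2]) - 1, each = d[1]) + 0.5) * st
    ltrb <- exp(pmin(matrix(bx[, , , 1], d[1] * d[2], 4), 8)) * st
    cls_m <- matrix(cl[, , , 1], d[1] * d[2], dim(cl)[3])
    prob <- 1 / (1 + exp(-cls_m))
    conf <- apply(prob, 1, max)
    cid <- max.col(prob, ties.method = "first")
    rows[[i]] <- data.frame(
      x1 = cx - ltrb[, 1], y1 = cy - ltrb[, 2],
      x2 = cx + ltrb[, 3], y2 = cy + ltrb[, 4],
      conf = conf, class_id = cid - 1L,
      scale = i, cell = seq_len(d[1] * d[2]))
    rows[[i]]$coef <- I(asplit(matrix(cf[, , , 1], d[1] * d[2], np), 1))
  }
  do.call(rbind, rows)
}

nms_boxes <- function(df, iou_thr) {
  keep <- logical(nrow(df))
  ord <- order(df$conf, decreasing = TRUE)
  taken <- list()
  for (i in ord) {
    bi <- c(df$x1[i], df$y1[i], df$x2[i], df$y2[i])
    ok <- TRUE
    for (bj in taken) if (box_iou(bi, bj) > iou_thr) { ok <- FALSE; break }
    if (ok) {
      keep[i] <- TRUE
      taken[[length(taken) + 1L]] <- bi
    }
  }
  df[keep, , drop = FALSE]
}

#' Predict stick instances in an image
#'
#' Runs the letterboxed forward pass, decodes anchor-free boxes, applies
#' class-agnostic non-maximum suppression and assembles per-instance
#' probability masks from the prototype bank. Instances are returned sorted
#' by descending confidence with boxes clipped to the image bounds.
#'
#' @param model assembled (materialised) contour model
#' @param image a `stick_image`
#' @param confidence_threshold minimum class confidence in (0, 1)
#' @param iou_nms NMS IoU threshold in (0, 1)
#' @return list of instance predictions: `box` (x1, y1, x2, y2), `class_id`
#'   (0 = pre, 1 = mid, 2 = post), `stage`, `confidence`, `mask`
#'   (probability `mask_raster` at image resolution)
#' @export
predict_instances <- function(model, image, confidence_threshold = 0.25,
                              iou_nms = 0.7) {
  stopifnot(confidence_threshold > 0, confidence_threshold < 1,
            iou_nms > 0, iou_nms < 1)
  nn_materialize(model)
  cfg <- model$meta$config
  lb <- letterbox_resize(image$pixels, cfg$input_size)
  x <- array(lb$img / 255, c(dim(lb$img)[1:2], 3, 1))
  tp <- tape_new()
  raw <- model$fwd(tp, op_leaf(tp, x), training = FALSE)
  df <- decode_outputs(model, raw, tp)
  df <- df[df$conf >= confidence_threshold, , drop = FALSE]
  if (nrow(df) == 0) return(list())
  df <- nms_boxes(df, iou_nms)
  df <- df[order(df$conf, decreasing = TRUE), , drop = FALSE]
  protos <- tp_val(tp, raw$protos)[, , , 1]   # (H/4, W/4, np)
  dp <- dim(protos)
  pm <- matrix(protos, dp[1] * dp[2], dp[3])
  H <- lb$src[1]; W <- lb$src[2]
  out <- lapply(seq_len(nrow(df)), function(i) {
    logit <- matrix(pm %*% df$coef[[i]], dp[1], dp[2])
    prob <- 1 / (1 + exp(-logit))
    # prototype grid covers the letterboxed canvas at 1/4 resolution
    full <- resize_img(prob, cfg$input_size[1], cfg$input_size[2], "bilinear")
    crop <- full[lb$pad[1] + seq_len(round(H * lb$scale)),
                 lb$pad[2] + seq_len(round(W * lb$scale)), drop = FALSE]
    mask <- resize_img(crop, H, W, "bilinear")
    box_lb <- c(df$x1[i], df$y1[i], df$x2[i], df$y2[i])
    box <- (box_lb - c(lb$pad[2], lb$pad[1], lb$pad[2], lb$pad[1])) / lb$scale
    box <- pmin(pmax(box, 0), c(W, H, W, H))
    list(box = box, class_id = df$class_id[i],
         stage = STAGES[df$class_id[i] + 1L],
         confidence = df$conf[i],
         mask = mask_raster(image$id, pmin(pmax(mask, 0), 1), "probability"))
  })
  out
}

#' Extract the region of interest selected by an instance mask
#'
#' Pixels outside the (binarised) mask are zeroed and the image is cropped to
#' the mask's bounding box; the returned offset locates the crop origin in
#' the original image so downstream masks can be mapped back.
#' @param image a `stick_image`
#' @param instance an instance prediction (or a binary `mask_raster`)
#' @param threshold binarisation threshold for probability masks
#' @return list(image, mask, offset = c(row, col) 0-based)
#' @export
extract_roi <- function(image, instance, threshold = 0.5) {
  mv <- if (inherits(instance, "mask_raster")) instance$values else instance$mask$values
  bin <- (mv >= threshold) * 1
  if (sum(bin) == 0) stop("no ROI: instance mask is empty")
  rows <- range(which(rowSums(bin) > 0))
  cols <- range(which(colSums(bin) > 0))
  px <- image$pixels
  for (c in 1:3) px[, , c] <- px[, , c] * bin
  crop <- px[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  list(image = stick_image(paste0(image$id, "_roi"), crop, image$stage,
                           image$background, image$exposure_tag),
       mask = mask_raster(image$id, bin[rows[1]:rows[2], cols[1]:cols[2]]),
       offset = c(rows[1] - 1L, cols[1] - 1L))
}

# ---- training --------------------------------------------------------------

contour_targets <- function(model, bundles) {
  cfg <- model$meta$config
  strides <- model$meta$strides
  lapply(bundles, function(b) {
    lb <- letterbox_resize(b$image$pixels, cfg$input_size)
    mv <- b$stick_mask$values
    rows <- range(which(rowSums(mv) > 0)); cols <- range(which(colSums(mv) > 0))
    # box in letterboxed coordinates
    box <- c(cols[1] - 1.5, rows[1] - 1.5, cols[2] - 0.5, rows[2] - 0.5) *
      lb$scale + c(lb$pad[2], lb$pad[1], lb$pad[2], lb$pad[1])
    cx <- (box[1] + box[3]) / 2; cy <- (box[2] + box[4]) / 2
    mlb <- letterbox_resize(array(rep(mv, 3), c(dim(mv), 3)), cfg$input_size, fill = 0)
    m4 <- resize_img(mlb$img[, , 1], cfg$input_size[1] %/% 4L,
                     cfg$input_size[2] %/% 4L, "bilinear")
    list(x = lb$img / 255, box = box, cx = cx, cy = cy,
         class_id = match(b$image$stage, STAGES) - 1L,
         mask4 = (m4 > 0.5) * 1)
  })
}

#' Train the contour model to overfit a small scene set
#'
#' Anchor-free single-positive assignment: on every pyramid level the cell
#' containing the ground-truth box centre is positive; classification uses
#' binary cross-entropy over all cells, box regression an L1 loss on
#' log-distances at positives, and the instance mask (prototypes times the
#' positive cell's coefficients) a BCE loss against the ground-truth mask at
#' 1/4 resolution.
#' @param model assembled contour model (materialised in place)
#' @param bundles list of `scene_bundle`s
#' @param steps optimisation steps (full batch)
#' @param lr Adam learning rate
#' @param verbose print loss every 25 steps
#' @return data.frame training log (step, loss)
#' @export
train_contour <- function(model, bundles, steps = 200L, lr = 2e-3,
                          verbose = FALSE) {
  nn_materialize(model)
  cfg <- model$meta$config
  strides <- model$meta$strides
  tg <- contour_targets(model, bundles)
  N <- length(tg)
  xb <- array(0, c(cfg$input_size[1], cfg$input_size[2], 3, N))
  for (i in seq_len(N)) xb[, , , i] <- tg[[i]]$x
  m4 <- array(0, c(cfg$input_size[1] %/% 4L, cfg$input_size[2] %/% 4L, 1, N))
  for (i in seq_len(N)) m4[, , 1, i] <- tg[[i]]$mask4
  log <- data.frame(step = integer(0), loss = numeric(0))
  for (s in seq_len(steps)) {
    tp <- tape_new()
    raw <- model$fwd(tp, op_leaf(tp, xb), training = TRUE)
    losses <- list(); wts <- numeric(0)
    for (sc in 1:3) {
      st <- strides[sc]
      bx <- raw$scales[[sc]]$box; cl <- raw$scales[[sc]]$cls
      dcl <- dim(tp_val(tp, cl))
      cls_t <- array(0, dcl)
      box_t <- array(0, dim(tp_val(tp, bx)))
      box_w <- array(0, dim(tp_val(tp, bx)))
      for (i in seq_len(N)) {
        ci <- pmin(pmax(floor(tg[[i]]$cx / st) + 1L, 1L), dcl[2])
        ri <- pmin(pmax(floor(tg[[i]]$cy / st) + 1L, 1L), dcl[1])
        cls_t[ri, ci, tg[[i]]$class_id + 1L, i] <- 1
        ccx <- (ci - 0.5) * st; ccy <- (ri - 0.5) * st
        dists <- pmax(c(ccx - tg[[i]]$box[1], ccy - tg[[i]]$box[2],
                        tg[[i]]$box[3] - ccx, tg[[i]]$box[4] - ccy), 1)
        box_t[ri, ci, , i] <- log(dists / st)
        box_w[ri, ci, , i] <- 1
      }
      losses <- c(losses, list(op_bce_logits(tp, cl, cls_t),
                               op_l1_masked(tp, bx, box_t, box_w)))
      wts <- c(wts, 1, 1)
    }
    # mask loss: positive-cell coefficients on every level share the
    # ground-truth mask, so whichever cell wins at inference is supervised
    for (sc in 1:3) {
      coef <- raw$scales[[sc]]$coef
      dcf <- dim(tp_val(tp, coef))
      mlogits <- vector("list", N)
      for (i in seq_len(N)) {
        st <- strides[sc]
        ci <- pmin(pmax(floor(tg[[i]]$cx / st) + 1L, 1L), dcf[2])
        ri <- pmin(pmax(floor(tg[[i]]$cy / st) + 1L, 1L), dcf[1])
        cvec <- op_slice_cell(tp, coef, ri, ci, i)
        pi <- op_slice_n(tp, raw$protos, i)
        mlogits[[i]] <- op_proto_combine(tp, pi, cvec)
      }
      mcat <- op_concat_n(tp, mlogits)
      losses <- c(losses, list(op_bce_logits(tp, mcat, m4),
                               op_dice_logits(tp, mcat, m4)))
      wts <- c(wts, 2, 1)
    }
    loss <- op_wsum(tp, losses, wts)
    tp_backward(tp, loss)
    adam_step(tp, lr = lr)
    log <- rbind(log, data.frame(step = s, loss = tp_val(tp, loss)))
    if (verbose && s %% 25 == 0)
      message(sprintf("step %d loss %.4f", s, tp_val(tp, loss)))
  }
  log
}

# pick the (row, col) cell of one sample: (H, W, C, N) -> (1, 1, C, 1)
op_slice_cell <- function(tp, xid, ri, ci, n) {
  force(xid)
  x <- tp$vals[[xid]]
  d <- dim(x)
  y <- x[ri, ci, , n, drop = FALSE]
  tp_push(tp, y, xid, function(grad) {
    gx <- array(0, d)
    gx[ri, ci, , n] <- grad
    list(gx)
  })
}

# slice one sample from the batch dimension
op_slice_n <- function(tp, xid, n) {
  force(xid)
  x <- tp$vals[[xid]]
  d <- dim(x)
  y <- x[, , , n, drop = FALSE]
  tp_push(tp, y, xid, function(grad) {
    gx <- array(0, d)
    gx[, , , n] <- grad
    list(gx)
  })
}

op_concat_n <- function(tp, ids) {
  ids <- as.integer(unlist(ids))
  xs <- lapply(ids, function(i) tp$vals[[i]])
  d <- dim(xs[[1]])
  y <- array(0, c(d[1], d[2], d[3], length(ids)))
  for (j in seq_along(ids)) y[, , , j] <- xs[[j]]
  tp_push(tp, y, ids, function(grad) {
    lapply(seq_along(ids), function(j) grad[, , , j, drop = FALSE])
  })
}

# mask logit = sum_k coef_k * proto_k  (single sample)
op_proto_combine <- function(tp, pid, cid) {
  force(pid); force(cid)
  p <- tp$vals[[pid]]          # (H, W, np, 1)
  cv <- tp$vals[[cid]]         # (1, 1, np, 1)
  d <- dim(p)
  pm <- matrix(p, d[1] * d[2], d[3])
  y <- array(pm %*% as.numeric(cv), c(d[1], d[2], 1, 1))
  tp_push(tp, y, c(pid, cid), function(grad) {
    gv <- as.numeric(grad)
    gp <- array(outer(gv, as.numeric(cv)), d)
    gc <- array(crossprod(pm, gv), dim(cv))
    list(gp, gc)
  })
}
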