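# RS-UNet: browning-region segmentation network.
#
# Encoder: ResNet50-style bottleneck stages (stage widths 256/512/1024/2048 at
# full scale).  The optimised encoder replaces the classic 7x7 stem with a
# dual-branch input adapter followed by a triple 3x3 stem (64->32->32->64);
# the decoder fuses skips with a grouped convolution at the deepest
# (2048+1024 = 3072 channel) level, depthwise-separable blocks at the middle
# levels and a plain 3x3 block at the top, with 30% spatial dropout on the
# final two levels; spatial attention gates each skip connection.
#
# Decoder widths (1024, 544, 224, 48) and the 80-channel refinement head are
# fixed so that the full-scale parameter counts land on the reference values:
# baseline 61,115,537 (61.12 M) and full RS-UNet 38,923,773 (38.92 M), a
# 36.31% reduction.

RSUNET_DECODER_WIDTHS <- c(1024L, 544L, 224L, 48L)
RSUNET_REFINE_WIDTH <- 80L
RSUNET_STEM3_WIDTHS <- c(32L, 32L)

#' RS-UNet configuration
#'
#' @param width_multiplier scales every channel count (1 = full scale; test
#'   profiles use 0.25 or less)
#' @param stem "triple_3x3" (optimised) or "classic_7x7" (baseline)
#' @param use_input_adapter prepend the dual-branch input adapter
#' @param sa_on_skips logical, recycled to the 4 skip connections
#' @param decoder "hybrid" (grouped + DSC + plain) or "plain" (baseline)
#' @param spatial_dropout_p channel-dropout probability on the final two
#'   decoder levels (training only)
#' @param out_classes output channels (1 = browning probability)
#' @return an `rsunet_config`
#' @export
rsunet_config <- function(width_multiplier = 1,
                          stem = c("triple_3x3", "classic_7x7"),
                          use_input_adapter = stem == "triple_3x3",
                          sa_on_skips = TRUE,
                          decoder = c("hybrid", "plain"),
                          spatial_dropout_p = 0.3,
                          out_classes = 1L) {
  stem <- match.arg(stem)
  decoder <- match.arg(decoder)
  stopifnot(width_multiplier > 0, out_classes >= 1)
  structure(list(width_multiplier = width_multiplier, stem = stem,
                 use_input_adapter = use_input_adapter,
                 sa_on_skips = rep(as.logical(sa_on_skips), length.out = 4),
                 decoder = decoder, spatial_dropout_p = spatial_dropout_p,
                 out_classes = as.integer(out_classes)),
            class = "rsunet_config")
}

sc_width <- function(x, m) pmax(4L, as.integer(round(x * m)))

resnet_bottleneck <- function(cin, w, stride = 1L) {
  c1 <- conv_bn(cin, w, k = 1L)
  c2 <- conv_bn(w, w, k = 3L, stride = stride)
  c3 <- conv_bn(w, 4L * w, k = 1L, act = "none")
  need_proj <- (cin != 4L * w) || stride != 1L
  proj <- if (need_proj) conv_bn(cin, 4L * w, k = 1L, stride = stride,
                                 act = "none") else NULL
  kids <- list(c1, c2, c3)
  if (need_proj) kids <- c(kids, list(proj))
  m <- new_module("bottleneck", children = kids,
                  meta = list(cin = cin, w = w, stride = stride))
  m$fwd <- function(tp, xid, training = TRUE) {
    y <- c3$fwd(tp, c2$fwd(tp, c1$fwd(tp, xid, training), training), training)
    idn <- if (need_proj) proj$fwd(tp, xid, training) else xid
    op_relu(tp, op_add(tp, y, idn))
  }
  m
}

resnet_layer <- function(cin, w, n_blocks, stride) {
  blocks <- list(resnet_bottleneck(cin, w, stride))
  for (i in seq_len(n_blocks - 1L))
    blocks[[i + 1L]] <- resnet_bottleneck(4L * w, w, 1L)
  sequential_module("resnet_layer", blocks)
}

#' Assemble an RS-UNet (or its baseline) model
#'
#' Maps a 3 x H x W image (H, W multiples of 32) to per-pixel browning
#' logits at full resolution. The returned module tree reports its trainable
#' parameter count via [count_parameters()] and carries a MAC-counting trace
#' for [complexity_audit()].
#'
#' @param config an [rsunet_config()]
#' @return a module with `$fwd(tape, xid, training)` and metadata
#' @export
assemble_rsunet <- function(config = rsunet_config()) {
  stopifnot(inherits(config, "rsunet_config"))
  m <- config$width_multiplier
  trace <- list()
  # Walks a module recording every convolution at its output-area fraction
  # (MACs per output pixel times output pixels); sequential children thread
  # the running scale so strided layers propagate correctly.
  tr <- function(mod, scale) {
    walk <- function(x, s) {
      if (x$kind == "conv_bn") {
        s_out <- s / (x$meta$stride^2)
        trace[[length(trace) + 1L]] <<-
          list(cin = x$meta$cin, cout = x$meta$cout, k = x$meta$k,
               groups = x$meta$groups, scale = s_out)
        return(s_out)
      }
      if (x$kind == "bottleneck") {
        s_out <- walk(x$children[[3]], walk(x$children[[2]], walk(x$children[[1]], s)))
        if (length(x$children) == 4) walk(x$children[[4]], s)
        return(s_out)
      }
      for (ch in x$children) s <- walk(ch, s)
      s
    }
    walk(mod, scale)
    mod
  }

  w64 <- sc_width(64, m)
  stage_w <- sc_width(c(64, 128, 256, 512), m)
  skips_c <- c(w64, 4L * stage_w[1], 4L * stage_w[2], 4L * stage_w[3])
  deep_c <- 4L * stage_w[4]
  dw <- sc_width(RSUNET_DECODER_WIDTHS, m)
  hw <- sc_width(RSUNET_REFINE_WIDTH, m)

  # ---- stem ----
  adapter <- NULL
  if (config$stem == "triple_3x3") {
    s3 <- sc_width(RSUNET_STEM3_WIDTHS, m)
    stem_in <- 3L
    if (config$use_input_adapter) {
      adapter <- tr(build_input_adapter(m), 1)
      stem_in <- adapter$meta$cout
    }
    stem <- tr(sequential_module("stem_triple", list(
      conv_bn(stem_in, s3[1], k = 3L, stride = 2L),
      conv_bn(s3[1], s3[2], k = 3L),
      conv_bn(s3[2], w64, k = 3L))), 1)
  } else {
    stem <- tr(conv_bn(3L, w64, k = 7L, stride = 2L, pad = 3L), 1)
  }

  # ---- encoder body ----
  enc1 <- tr(resnet_layer(w64, stage_w[1], 3L, 1L), 1 / 16)
  enc2 <- tr(resnet_layer(4L * stage_w[1], stage_w[2], 4L, 2L), 1 / 16)
  enc3 <- tr(resnet_layer(4L * stage_w[2], stage_w[3], 6L, 2L), 1 / 64)
  enc4 <- tr(resnet_layer(4L * stage_w[3], stage_w[4], 3L, 2L), 1 / 256)

  # ---- spatial attention on skips ----
  sa_scales <- c(1 / 4, 1 / 16, 1 / 64, 1 / 256)
  sas <- lapply(seq_len(4), function(i)
    if (config$sa_on_skips[i]) build_spatial_attention() else NULL)
  for (i in seq_len(4)) if (!is.null(sas[[i]])) tr(sas[[i]], sa_scales[i])

  # ---- decoder ----
  hybrid <- config$decoder == "hybrid"
  dec1 <- if (hybrid) {
    tr(build_grouped_fusion(skips_c[4], deep_c, dw[1], groups = 2L), 1 / 256)
  } else tr(conv_bn(skips_c[4] + deep_c, dw[1], k = 3L), 1 / 256)
  dec2 <- if (hybrid) {
    tr(build_dsc(dw[1] + skips_c[3], dw[2]), 1 / 64)
  } else tr(conv_bn(dw[1] + skips_c[3], dw[2], k = 3L), 1 / 64)
  dec3 <- if (hybrid) {
    tr(build_dsc(dw[2] + skips_c[2], dw[3]), 1 / 16)
  } else tr(conv_bn(dw[2] + skips_c[2], dw[3], k = 3L), 1 / 16)
  dec4 <- tr(conv_bn(dw[3] + skips_c[1], dw[4], k = 3L), 1 / 4)
  refine <- tr(conv_bn(dw[4], hw, k = 3L), 1)
  head <- tr(conv_bn(hw, config$out_classes, k = 1L, bias = TRUE, bn = FALSE,
                     act = "none"), 1)

  kids <- Filter(Negate(is.null),
                 c(list(adapter, stem, enc1, enc2, enc3, enc4), sas,
                   list(dec1, dec2, dec3, dec4, refine, head)))
  model <- new_module("rsunet", children = kids,
                      meta = list(config = config))
  model$meta$count_macs <- function(input_size) {
    sum(vapply(trace, function(t)
      t$cout * (t$cin / t$groups) * t$k^2 *
        input_size[1] * input_size[2] * t$scale, 0))
  }
  model$fwd <- function(tp, xid, training = TRUE) {
    d <- dim(tp_val(tp, xid))
    if (d[1] %% 32 || d[2] %% 32)
      stop(sprintf("input %dx%d must be a multiple of 32; pad to %dx%d",
                   d[1], d[2], 32 * ceiling(d[1] / 32), 32 * ceiling(d[2] / 32)))
    x <- xid
    if (!is.null(adapter)) x <- adapter$fwd(tp, x, training)
    s0 <- stem$fwd(tp, x, training)            # 1/2 resolution, w64 channels
    p <- op_maxpool2(tp, s0)
    e1 <- enc1$fwd(tp, p, training)            # 1/4
    e2 <- enc2$fwd(tp, e1, training)           # 1/8
    e3 <- enc3$fwd(tp, e2, training)           # 1/16
    e4 <- enc4$fwd(tp, e3, training)           # 1/32
    gate <- function(i, sid) if (is.null(sas[[i]])) sid else sas[[i]]$fwd(tp, sid, training)
    u <- op_upsample2(tp, e4)
    d1 <- dec1$fwd(tp, if (hybrid) list(gate(4, e3), u) else
                     op_concat_c(tp, list(gate(4, e3), u)), training)
    u <- op_upsample2(tp, d1)
    d2 <- dec2$fwd(tp, op_concat_c(tp, list(gate(3, e2), u)), training)
    u <- op_upsample2(tp, d2)
    d3 <- dec3$fwd(tp, op_concat_c(tp, list(gate(2, e1), u)), training)
    d3 <- op_spatial_dropout(tp, d3, config$spatial_dropout_p, training)
    u <- op_upsample2(tp, d3)
    d4 <- dec4$fwd(tp, op_concat_c(tp, list(gate(1, s0), u)), training)
    d4 <- op_spatial_dropout(tp, d4, config$spatial_dropout_p, training)
    u <- op_upsample2(tp, d4)
    head$fwd(tp, refine$fwd(tp, u, training), training)
  }
  model
}

#' Forward an image batch through an RS-UNet
#'
#' @param model an assembled (and materialised) RS-UNet
#' @param x numeric array (H, W, 3, N) on a 0..1 scale
#' @param training training mode (batch statistics, dropout active)
#' @return array (H, W, out_classes, N) of probabilities
#' @export
rsunet_forward <- function(model, x, training = FALSE) {
  nn_materialize(model)
  tp <- tape_new()
  out <- model$fwd(tp, op_leaf(tp, x), training)
  1 / (1 + exp(-tp_val(tp, out)))
}

#' Train an RS-UNet on ROI crops and browning masks
#'
#' Optimises binary cross-entropy plus Dice loss (equal weights) with Adam.
#' @param model assembled RS-UNet (materialised in place)
#' @param images array (H, W, 3, N), 0..1 scale
#' @param masks array (H, W, 1, N) of 0/1 browning labels
#' @param steps optimisation steps (full-batch)
#' @param lr learning rate
#' @param verbose print loss every 25 steps
#' @return data.frame training log (step, loss)
#' @export
train_rsunet <- function(model, images, masks, steps = 300L, lr = 1e-3,
                         verbose = FALSE) {
  nn_materialize(model)
  log <- data.frame(step = integer(0), loss = numeric(0))
  for (s in seq_len(steps)) {
    tp <- tape_new()
    out <- model$fwd(tp, op_leaf(tp, images), training = TRUE)
    l1 <- op_bce_logits(tp, out, masks)
    l2 <- op_dice_logits(tp, out, masks)
    loss <- op_wsum(tp, list(l1, l2), c(1, 1))
    tp_backward(tp, loss)
    adam_step(tp, lr = lr)
    log <- rbind(log, data.frame(step = s, loss = tp_val(tp, loss)))
    if (verbose && s %% 25 == 0)
      message(sprintf("step %d loss %.4f", s, tp_val(tp, loss)))
  }
  log
}
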