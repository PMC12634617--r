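# Network building blocks.
#
# A module is an environment carrying declared parameter shapes (so parameter
# counts are available without allocating full-scale weights), lazy
# initialisers, and a forward closure operating on an autograd tape.
# count_parameters() walks the module tree analytically; materialisation
# happens only when a forward pass is actually run (test-scale profiles).

new_module <- function(kind, shapes = list(), inits = list(), fwd = NULL,
                       children = list(), meta = list(), trainable = TRUE) {
  m <- new.env(parent = emptyenv())
  m$kind <- kind
  m$shapes <- shapes
  m$inits <- inits
  m$params <- NULL
  m$buffers <- list()
  m$opt <- list()
  m$fwd <- fwd
  m$children <- children
  m$meta <- meta
  m$trainable <- trainable
  class(m) <- "sv_module"
  m
}

#' Count trainable parameters of a module tree
#'
#' Sums the element counts of every declared trainable parameter, matching
#' hand arithmetic on single layers (e.g. a 3x3 convolution 3->16 with bias
#' holds 16*3*3*3 + 16 = 448 weights). Frozen modules contribute zero.
#'
#' @param model an object built by [assemble_rsunet()],
#'   [assemble_contour_model()] or any single building block
#' @return integer number of trainable parameters
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "sv_module"))
  n <- 0
  if (isTRUE(model$trainable)) {
    n <- sum(vapply(model$shapes, prod, 0))
  }
  for (ch in model$children) n <- n + count_parameters(ch)
  as.integer(round(n))
}

#' Freeze or unfreeze a module tree
#' @param model a module
#' @param trainable logical
#' @return the module, modified in place
#' @export
nn_freeze <- function(model, trainable = FALSE) {
  model$trainable <- trainable
  for (ch in model$children) nn_freeze(ch, trainable)
  invisible(model)
}

#' Materialise module parameters
#'
#' Allocates and initialises every declared parameter (He-normal weights,
#' unit/zero affine terms). Uses the current R RNG state; seed beforehand for
#' reproducibility.
#' @param model a module
#' @return the module, modified in place
#' @export
nn_materialize <- function(model) {
  if (is.null(model$params) && length(model$shapes)) {
    model$params <- lapply(names(model$shapes), function(pn) model$inits[[pn]]())
    names(model$params) <- names(model$shapes)
  }
  for (ch in model$children) nn_materialize(ch)
  invisible(model)
}

he_init <- function(shape, fan_in) {
  array(stats::rnorm(prod(shape), 0, sqrt(2 / fan_in)), shape)
}

run_act <- function(tp, xid, act, mod = NULL) {
  switch(act,
    relu = op_relu(tp, xid),
    sigmoid = op_sigmoid(tp, xid),
    dynamic_relu = op_dynrelu(tp, xid,
                              op_param(tp, mod, "act_a"),
                              op_param(tp, mod, "act_b")),
    none = xid,
    stop("unknown activation: ", act))
}

# y = max(a_c * x, b_c * x): channel-wise gated activation with learned
# slopes; (a, b) = (1, 0) reduces it to plain ReLU.
op_dynrelu <- function(tp, xid, aid, bid) {
  force(xid); force(aid); force(bid)
  x <- tp$vals[[xid]]
  a <- tp$vals[[aid]]
  b <- tp$vals[[bid]]
  d <- dim(x); C <- d[3]
  ae <- array(rep(a, each = d[1] * d[2]), d)
  be <- array(rep(b, each = d[1] * d[2]), d)
  ax <- ae * x
  bx <- be * x
  sel <- ax >= bx
  y <- ifelse(sel, ax, bx)
  tp_push(tp, y, c(xid, aid, bid), function(grad) {
    gx <- grad * ifelse(sel, ae, be)
    gxa <- grad * x * sel
    gxb <- grad * x * (!sel)
    csum <- function(z) colSums(matrix(aperm(z, c(1, 2, 4, 3)), ncol = C))
    list(gx, csum(gxa), csum(gxb))
  })
}

# ---- convolution block -----------------------------------------------------

#' @keywords internal
conv_bn <- function(cin, cout, k = 3L, stride = 1L, pad = k %/% 2L,
                    groups = 1L, bias = FALSE, bn = TRUE, act = "relu") {
  if (cin %% groups || cout %% groups)
    stop("groups must divide both channel counts")
  fan_in <- k * k * cin / groups
  shapes <- list(w = c(cout, fan_in))
  inits <- list(w = function() he_init(c(cout, fan_in), fan_in))
  if (bias) {
    shapes$b <- cout
    inits$b <- function() numeric(cout)
  }
  if (bn) {
    shapes$gamma <- cout
    shapes$beta <- cout
    inits$gamma <- function() rep(1, cout)
    inits$beta <- function() numeric(cout)
  }
  if (act == "dynamic_relu") {
    shapes$act_a <- cout
    shapes$act_b <- cout
    inits$act_a <- function() rep(1, cout)
    inits$act_b <- function() numeric(cout)
  }
  m <- new_module("conv_bn", shapes, inits,
                  meta = list(cin = cin, cout = cout, k = k, stride = stride,
                              pad = pad, groups = groups, bn = bn, act = act))
  m$buffers <- list(rmean = numeric(cout), rvar = rep(1, cout))
  m$fwd <- function(tp, xid, training = TRUE) {
    wid <- op_param(tp, m, "w")
    bid <- if (bias) op_param(tp, m, "b") else NULL
    y <- op_conv(tp, xid, wid, bid, k = k, stride = stride, pad = pad,
                 groups = groups)
    if (bn) y <- op_bn(tp, y, op_param(tp, m, "gamma"),
                       op_param(tp, m, "beta"), m, training)
    run_act(tp, y, act, m)
  }
  m
}

sequential_module <- function(kind, mods) {
  m <- new_module(kind, children = mods)
  m$fwd <- function(tp, xid, training = TRUE) {
    for (ch in mods) xid <- ch$fwd(tp, xid, training)
    xid
  }
  m
}

# ---- GhostConv -------------------------------------------------------------

#' Ghost convolution block
#'
#' Produces `out_channels / ratio` feature maps with a primary convolution and
#' generates the remaining channels with a cheap depthwise convolution of the
#' primary output, then concatenates. `ratio = 1` degenerates to a standard
#' convolution.
#'
#' @param in_channels,out_channels channel counts
#' @param primary_kernel kernel size of the primary convolution
#' @param ratio ghost ratio (>= 1); `out_channels` must be divisible by it
#' @param cheap_kernel kernel size of the cheap depthwise convolution
#' @param stride stride of the primary convolution
#' @param bias use bias terms (usual when `normalization = FALSE`)
#' @param normalization append batch normalisation to both branches
#' @param act activation name
#' @return a module; see [count_parameters()]
#' @export
build_ghost_conv <- function(in_channels, out_channels, primary_kernel = 3L,
                             ratio = 2L, cheap_kernel = 3L, stride = 1L,
                             bias = !normalization, normalization = TRUE,
                             act = "relu") {
  if (ratio < 1L) stop("ratio must be >= 1")
  if (out_channels %% ratio)
    stop("out_channels must be divisible by ratio")
  if (ratio == 1L) {
    m <- conv_bn(in_channels, out_channels, k = primary_kernel, stride = stride,
                 bias = bias, bn = normalization, act = act)
    m$kind <- "ghost_conv"
    return(m)
  }
  hidden <- out_channels %/% ratio
  cheap_out <- out_channels - hidden
  if (cheap_out %% hidden)
    stop("cheap branch output must be a multiple of the primary output")
  primary <- conv_bn(in_channels, hidden, k = primary_kernel, stride = stride,
                     bias = bias, bn = normalization, act = act)
  # depthwise: each of the `hidden` primary maps spawns ratio-1 cheap maps
  cheap <- conv_bn(hidden, cheap_out, k = cheap_kernel, stride = 1L,
                   groups = hidden, bias = bias, bn = normalization, act = act)
  m <- new_module("ghost_conv", children = list(primary, cheap),
                  meta = list(cin = in_channels, cout = out_channels,
                              ratio = ratio))
  m$fwd <- function(tp, xid, training = TRUE) {
    p <- primary$fwd(tp, xid, training)
    q <- cheap$fwd(tp, p, training)
    op_concat_c(tp, list(p, q))
  }
  m
}

# ---- VanillaNet block ------------------------------------------------------

#' VanillaNet-style block
#'
#' A minimalist non-residual block: grouped 3x3 convolution, batch
#' normalisation and a (dynamic) ReLU, with optional 2x downsampling by max
#' pooling. No residual addition, attention or pyramid structure.
#'
#' @param in_channels,out_channels channel counts
#' @param groups group count; must divide both channel counts
#' @param downsample halve the spatial dimensions with 2x2 max pooling
#' @param activation `"dynamic_relu"` (2 learned slopes per channel) or
#'   `"relu"`
#' @return a module
#' @export
build_vanilla_block <- function(in_channels, out_channels, groups = 2L,
                                downsample = FALSE, activation = "dynamic_relu") {
  conv <- conv_bn(in_channels, out_channels, k = 3L, groups = groups,
                  act = activation)
  m <- new_module("vanilla_block", children = list(conv),
                  meta = list(downsample = downsample))
  m$fwd <- function(tp, xid, training = TRUE) {
    y <- conv$fwd(tp, xid, training)
    if (downsample) y <- op_maxpool2(tp, y)
    y
  }
  m
}

# ---- depthwise-separable convolution ---------------------------------------

#' Depthwise-separable convolution block
#'
#' Depthwise k x k convolution per channel followed by a 1x1 pointwise
#' convolution reorganising channels.
#'
#' @param in_channels,out_channels channel counts
#' @param k depthwise kernel size
#' @param bn append batch normalisation after both stages
#' @param act activation after the pointwise stage
#' @return a module
#' @export
build_dsc <- function(in_channels, out_channels, k = 3L, bn = TRUE,
                      act = "relu") {
  dw <- conv_bn(in_channels, in_channels, k = k, groups = in_channels,
                bn = bn, act = "none")
  pw <- conv_bn(in_channels, out_channels, k = 1L, bn = bn, act = act)
  m <- new_module("dsc", children = list(dw, pw))
  m$fwd <- function(tp, xid, training = TRUE) {
    pw$fwd(tp, dw$fwd(tp, xid, training), training)
  }
  m
}

# ---- grouped fusion --------------------------------------------------------

#' Grouped skip-fusion block
#'
#' Concatenates a skip tensor with an upsampled decoder tensor and applies a
#' grouped 3x3 convolution, letting colour and texture channel groups be
#' modelled separately.
#' @param c_skip,c_up input channel counts
#' @param out_channels output channels
#' @param groups group count; must divide `c_skip + c_up`
#' @return a module whose forward takes `list(skip_id, up_id)`
#' @export
build_grouped_fusion <- function(c_skip, c_up, out_channels, groups = 2L) {
  cin <- c_skip + c_up
  if (cin %% groups) stop("groups must divide the concatenated channel count")
  conv <- conv_bn(cin, out_channels, k = 3L, groups = groups)
  m <- new_module("grouped_fusion", children = list(conv))
  m$fwd <- function(tp, ids, training = TRUE) {
    conv$fwd(tp, op_concat_c(tp, ids), training)
  }
  m
}

# ---- spatial attention -----------------------------------------------------

#' Spatial attention gate
#'
#' Channel-wise mean and max maps are concatenated (2 channels), passed
#' through a 7x7 convolution with bias (7*7*2 + 1 = 99 parameters) and a
#' sigmoid, and the resulting map in (0,1) multiplies the input features.
#' @param conv_kernel kernel size of the attention convolution
#' @return a module
#' @export
build_spatial_attention <- function(conv_kernel = 7L) {
  conv <- conv_bn(2L, 1L, k = conv_kernel, bias = TRUE, bn = FALSE,
                  act = "none")
  m <- new_module("spatial_attention", children = list(conv))
  m$fwd <- function(tp, xid, training = TRUE) {
    mn <- op_chan_mean(tp, xid)
    mx <- op_chan_max(tp, xid)
    a <- conv$fwd(tp, op_concat_c(tp, list(mx, mn)), training)
    op_mul_bcast(tp, xid, op_sigmoid(tp, a))
  }
  m
}

# ---- input adapter ---------------------------------------------------------

#' Dual-branch input adapter
#'
#' An RGB branch (3x3 convolution to `16 * scale` channels) and an edge branch
#' operating on the difference between the image and its 3x3 average pooling,
#' fused by a 3x3 convolution to `64 * scale` channels. All three convolutions
#' carry biases; at full scale the adapter holds 448 + 448 + 18,496 = 19,392
#' trainable parameters.
#' @param scale width multiplier (1 = full scale)
#' @return a module
#' @export
build_input_adapter <- function(scale = 1) {
  cb <- max(4L, as.integer(round(16 * scale)))
  cf <- max(8L, as.integer(round(64 * scale)))
  rgb <- conv_bn(3L, cb, k = 3L, bias = TRUE, bn = FALSE, act = "relu")
  edge <- conv_bn(3L, cb, k = 3L, bias = TRUE, bn = FALSE, act = "relu")
  fuse <- conv_bn(2L * cb, cf, k = 3L, bias = TRUE, bn = FALSE, act = "relu")
  m <- new_module("input_adapter", children = list(rgb, edge, fuse),
                  meta = list(cout = cf))
  m$fwd <- function(tp, xid, training = TRUE) {
    fr <- rgb$fwd(tp, xid, training)
    av <- op_avgpool3(tp, xid)
    fe <- edge$fwd(tp, op_sub(tp, xid, av), training)
    fuse$fwd(tp, op_concat_c(tp, list(fr, fe)), training)
  }
  m
}

# 3x3 stride-1 average pooling (zero padded), as a fixed depthwise convolution.
op_avgpool3 <- function(tp, xid) {
  force(xid)
  C <- dim(tp$vals[[xid]])[3]
  wid <- op_leaf(tp, matrix(1 / 9, C, 9))
  op_conv(tp, xid, wid, NULL, k = 3L, stride = 1L, pad = 1L, groups = C)
}

#' Spatial dropout
#'
#' Zeroes whole feature channels independently with probability `p` during
#' training (rescaling survivors by 1/(1-p)); identity in evaluation mode.
#' @param x array with dim (H, W, C, N)
#' @param p drop probability in [0, 1)
#' @param training logical
#' @return array of the same shape
#' @export
spatial_dropout <- function(x, p = 0.3, training = TRUE) {
  stopifnot(p >= 0, p < 1)
  tp <- tape_new()
  tp_val(tp, op_spatial_dropout(tp, op_leaf(tp, x), p, training))
}
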