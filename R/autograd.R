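# Tape-based reverse-mode automatic differentiation over dense 4-d arrays.
#
# Tensors are numeric arrays with dim = c(H, W, C, N).  A tape records one
# forward pass; tp_backward() walks it in reverse accumulating gradients.
# Convolution im2col/col2im and max-pooling kernels live in src/convops.cpp;
# everything else is vectorised R.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$vals <- vector("list", 256L)
  tp$nodes <- vector("list", 256L)
  tp$param_refs <- list()
  tp
}

tp_push <- function(tp, val, inputs = integer(0), backward = NULL) {
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$vals)) {
    length(tp$vals) <- 2L * length(tp$vals)
    length(tp$nodes) <- 2L * length(tp$nodes)
  }
  tp$vals[[tp$n]] <- val
  tp$nodes[[tp$n]] <- list(inputs = inputs, backward = backward)
  tp$n
}

tp_val <- function(tp, id) {
  force(id)
  tp$vals[[id]]
}

op_leaf <- function(tp, val) tp_push(tp, val)

# Register a module parameter on the tape so the optimizer can find its grad.
op_param <- function(tp, mod, pname) {
  id <- tp_push(tp, mod$params[[pname]])
  if (isTRUE(mod$trainable)) {
    tp$param_refs[[length(tp$param_refs) + 1L]] <-
      list(mod = mod, pname = pname, id = id)
  }
  id
}

tp_backward <- function(tp, id, seed = NULL) {
  grads <- vector("list", tp$n)
  v <- tp$vals[[id]]
  grads[[id]] <- if (is.null(seed)) array(1, dim = dim(v) %||% length(v)) else seed
  for (i in seq(id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tp$nodes[[i]]
    if (is.null(nd$backward)) next
    gin <- nd$backward(g)
    for (j in seq_along(nd$inputs)) {
      k <- nd$inputs[j]
      if (is.null(gin[[j]])) next
      grads[[k]] <- if (is.null(grads[[k]])) gin[[j]] else grads[[k]] + gin[[j]]
    }
  }
  tp$grads <- grads
  invisible(grads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- convolution -----------------------------------------------------------

conv_out_hw <- function(H, W, k, stride, pad) {
  c((H + 2L * pad - k) %/% stride + 1L, (W + 2L * pad - k) %/% stride + 1L)
}

# x: (H,W,C,N); w: matrix (Cout, k*k*Cin/groups), rows blocked by group.
op_conv <- function(tp, xid, wid, bid = NULL, k, stride = 1L, pad = 0L,
                    groups = 1L) {
  force(xid); force(wid); force(bid)
  x <- tp$vals[[xid]]
  w <- tp$vals[[wid]]
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Cout <- nrow(w)
  ohw <- conv_out_hw(H, W, k, stride, pad)
  b <- if (!is.null(bid)) as.numeric(tp$vals[[bid]]) else NULL
  fw <- .conv_fwd(as.numeric(x), H, W, C, N, w, b, k, stride, pad, groups)
  y <- array(fw$y, c(ohw[1], ohw[2], Cout, N))
  ids <- c(xid, wid, if (!is.null(bid)) bid)
  tp_push(tp, y, ids, function(grad) {
    bw <- .conv_bwd(as.numeric(grad), fw$cols, w, H, W, C, N, k, stride, pad,
                    groups, !is.null(b))
    out <- list(array(bw$gx, d), bw$gw)
    if (!is.null(b)) out <- c(out, list(as.numeric(bw$gb)))
    out
  })
}

# ---- batch normalisation ---------------------------------------------------

# mod carries buffers$rmean / buffers$rvar; gamma/beta arrive as tape values.
op_bn <- function(tp, xid, gid, bid, mod, training = TRUE,
                  momentum = 0.1, eps = 1e-5) {
  force(xid); force(gid); force(bid)
  x <- tp$vals[[xid]]
  gam <- tp$vals[[gid]]
  bet <- tp$vals[[bid]]
  d <- dim(x); C <- d[3]; N <- d[4]; HW <- d[1] * d[2]
  m <- HW * N
  xm <- matrix(x, HW)                     # columns are (c, n) pairs
  if (training) {
    mu <- rowMeans(matrix(colMeans(xm), C, N))
    va <- rowMeans(matrix(colMeans(xm * xm), C, N)) - mu^2
    mod$buffers$rmean <- (1 - momentum) * mod$buffers$rmean + momentum * mu
    mod$buffers$rvar <- (1 - momentum) * mod$buffers$rvar + momentum * va
  } else {
    mu <- mod$buffers$rmean
    va <- mod$buffers$rvar
  }
  istd <- 1 / sqrt(va + eps)
  mu_cn <- rep(rep(mu, N), each = HW)
  istd_cn <- rep(rep(istd, N), each = HW)
  xhat <- (as.numeric(x) - mu_cn) * istd_cn
  y <- array(xhat * rep(rep(gam, N), each = HW) + rep(rep(bet, N), each = HW), d)
  tp_push(tp, y, c(xid, gid, bid), function(grad) {
    gv <- as.numeric(grad)
    percn <- function(z) rowSums(matrix(colSums(matrix(z, HW)), C, N))
    dgam <- percn(gv * xhat)
    dbet <- percn(gv)
    if (training) {
      dx <- gv - rep(rep(dbet / m, N), each = HW) -
        xhat * rep(rep(dgam / m, N), each = HW)
      dx <- dx * rep(rep(gam * istd, N), each = HW)
    } else {
      dx <- gv * rep(rep(gam * istd, N), each = HW)
    }
    list(array(dx, d), dgam, dbet)
  })
}

# ---- pointwise ops ---------------------------------------------------------

op_relu <- function(tp, xid) {
  force(xid)
  x <- tp$vals[[xid]]
  y <- pmax(x, 0)
  mask <- x > 0
  tp_push(tp, y, xid, function(grad) list(grad * mask))
}

op_sigmoid <- function(tp, xid) {
  force(xid)
  x <- tp$vals[[xid]]
  y <- 1 / (1 + exp(-x))
  tp_push(tp, y, xid, function(grad) list(grad * y * (1 - y)))
}

op_add <- function(tp, aid, bid) {
  force(aid); force(bid)
  y <- tp$vals[[aid]] + tp$vals[[bid]]
  tp_push(tp, y, c(aid, bid), function(grad) list(grad, grad))
}

op_sub <- function(tp, aid, bid) {
  force(aid); force(bid)
  y <- tp$vals[[aid]] - tp$vals[[bid]]
  tp_push(tp, y, c(aid, bid), function(grad) list(grad, -grad))
}

# elementwise product with channel broadcast: m has 1 channel.
op_mul_bcast <- function(tp, xid, mid) {
  force(xid); force(mid)
  x <- tp$vals[[xid]]
  m <- tp$vals[[mid]]
  C <- dim(x)[3]
  me <- m[, , rep(1L, C), , drop = FALSE]
  tp_push(tp, x * me, c(xid, mid), function(grad) {
    gm2 <- grad * x
    gm <- aperm(gm2, c(3, 1, 2, 4))
    gm <- colSums(matrix(gm, C))
    list(grad * me, array(gm, dim(m)))
  })
}

op_concat_c <- function(tp, ids) {
  ids <- as.integer(unlist(ids))
  xs <- lapply(ids, function(i) tp$vals[[i]])
  cs <- vapply(xs, function(x) dim(x)[3], 0)
  d <- dim(xs[[1]])
  y <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (x in xs) {
    y[, , (at + 1L):(at + dim(x)[3]), ] <- x
    at <- at + dim(x)[3]
  }
  tp_push(tp, y, ids, function(grad) {
    out <- vector("list", length(ids))
    at <- 0L
    for (j in seq_along(ids)) {
      out[[j]] <- grad[, , (at + 1L):(at + cs[j]), , drop = FALSE]
      at <- at + cs[j]
    }
    out
  })
}

op_slice_c <- function(tp, xid, ch) {
  force(xid)
  x <- tp$vals[[xid]]
  y <- x[, , ch, , drop = FALSE]
  tp_push(tp, y, xid, function(grad) {
    gx <- array(0, dim(x))
    gx[, , ch, ] <- grad
    list(gx)
  })
}

op_chan_mean <- function(tp, xid) {
  force(xid)
  x <- tp$vals[[xid]]
  d <- dim(x); C <- d[3]
  y <- array(colSums(matrix(aperm(x, c(3, 1, 2, 4)), C)) / C,
             c(d[1], d[2], 1, d[4]))
  tp_push(tp, y, xid, function(grad) {
    list(grad[, , rep(1L, C), , drop = FALSE] / C)
  })
}

op_chan_max <- function(tp, xid) {
  force(xid)
  x <- tp$vals[[xid]]
  d <- dim(x); C <- d[3]
  y <- x[, , 1, , drop = FALSE]
  arg <- array(1L, dim(y))
  if (C > 1) for (c in 2:C) {
    xc <- x[, , c, , drop = FALSE]
    upd <- xc > y
    y[upd] <- xc[upd]
    arg[upd] <- c
  }
  tp_push(tp, y, xid, function(grad) {
    gx <- array(0, d)
    for (c in seq_len(C)) {
      sel <- arg == c
      gc <- array(0, dim(y))
      gc[sel] <- grad[sel]
      gx[, , c, ] <- gc
    }
    list(gx)
  })
}

# ---- resampling ------------------------------------------------------------

.upmat_cache <- new.env(parent = emptyenv())

# 2x upsampling matrix (2n x n); bilinear uses half-pixel centres.
upsample2_matrix <- function(n, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  key <- paste(mode, n)
  if (!is.null(.upmat_cache[[key]])) return(.upmat_cache[[key]])
  A <- matrix(0, 2L * n, n)
  if (mode == "nearest") {
    A[cbind(seq_len(2L * n), rep(seq_len(n), each = 2L))] <- 1
  } else {
    for (i in seq_len(2L * n)) {
      s <- (i - 0.5) / 2 - 0.5          # 0-based source coordinate
      f <- floor(s)
      t <- s - f
      i0 <- min(max(f, 0), n - 1)
      i1 <- min(max(f + 1, 0), n - 1)
      A[i, i0 + 1] <- A[i, i0 + 1] + (1 - t)
      A[i, i1 + 1] <- A[i, i1 + 1] + t
    }
  }
  .upmat_cache[[key]] <- A
  A
}

op_upsample2 <- function(tp, xid, mode = "bilinear") {
  force(xid)
  x <- tp$vals[[xid]]
  d <- dim(x)
  Ah <- upsample2_matrix(d[1], mode)
  Aw <- upsample2_matrix(d[2], mode)
  up <- function(z, dd) {
    y <- Ah %*% matrix(z, dd[1])
    y <- array(y, c(2L * dd[1], dd[2], dd[3], dd[4]))
    y <- aperm(y, c(2, 1, 3, 4))
    y <- Aw %*% matrix(y, dd[2])
    aperm(array(y, c(2L * dd[2], 2L * dd[1], dd[3], dd[4])), c(2, 1, 3, 4))
  }
  down <- function(g, dd) {
    z <- t(Ah) %*% matrix(g, 2L * dd[1])
    z <- array(z, c(dd[1], 2L * dd[2], dd[3], dd[4]))
    z <- aperm(z, c(2, 1, 3, 4))
    z <- t(Aw) %*% matrix(z, 2L * dd[2])
    aperm(array(z, c(dd[2], dd[1], dd[3], dd[4])), c(2, 1, 3, 4))
  }
  tp_push(tp, up(x, d), xid, function(grad) list(down(grad, d)))
}

op_maxpool2 <- function(tp, xid) {
  force(xid)
  x <- tp$vals[[xid]]
  d <- dim(x)
  r <- .maxpool2_fwd(as.numeric(x), d[1], d[2], d[3], d[4])
  y <- array(r$out, c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4]))
  tp_push(tp, y, xid, function(grad) {
    list(array(.maxpool2_bwd(as.numeric(grad), r$argmax, prod(d)), d))
  })
}

# ---- regularisation --------------------------------------------------------

# Channel-wise (spatial) dropout; draws from the R RNG.
op_spatial_dropout <- function(tp, xid, p, training = TRUE) {
  force(xid)
  x <- tp$vals[[xid]]
  if (!training || p <= 0) return(tp_push(tp, x, xid, function(grad) list(grad)))
  d <- dim(x)
  keep <- array(stats::runif(d[3] * d[4]) >= p, c(1, 1, d[3], d[4]))
  scale <- 1 / (1 - p)
  mask <- keep[rep(1L, d[1]), rep(1L, d[2]), , , drop = FALSE] * scale
  tp_push(tp, x * mask, xid, function(grad) list(grad * mask))
}

# ---- losses (scalar outputs) -----------------------------------------------

op_bce_logits <- function(tp, xid, target, weight = NULL) {
  force(xid)
  z <- tp$vals[[xid]]
  w <- if (is.null(weight)) 1 else weight
  n <- if (is.null(weight)) length(z) else sum(weight)
  l <- sum(w * (pmax(z, 0) - z * target + log1p(exp(-abs(z))))) / n
  tp_push(tp, l, xid, function(grad) {
    p <- 1 / (1 + exp(-z))
    list(as.numeric(grad) * w * (p - target) / n)
  })
}

op_dice_logits <- function(tp, xid, target, smooth = 1) {
  force(xid)
  z <- tp$vals[[xid]]
  p <- 1 / (1 + exp(-z))
  num <- 2 * sum(p * target) + smooth
  den <- sum(p) + sum(target) + smooth
  l <- 1 - num / den
  tp_push(tp, l, xid, function(grad) {
    dp <- -(2 * target * den - num) / den^2
    list(as.numeric(grad) * dp * p * (1 - p))
  })
}

op_l1_masked <- function(tp, xid, target, mask) {
  force(xid)
  x <- tp$vals[[xid]]
  n <- max(sum(mask), 1)
  l <- sum(abs(x - target) * mask) / n
  tp_push(tp, l, xid, function(grad) {
    list(as.numeric(grad) * sign(x - target) * mask / n)
  })
}

op_wsum <- function(tp, ids, weights) {
  ids <- as.integer(unlist(ids))
  y <- 0
  for (j in seq_along(ids)) y <- y + weights[j] * tp$vals[[ids[[j]]]]
  tp_push(tp, y, ids, function(grad) {
    lapply(weights, function(w) as.numeric(grad) * w)
  })
}

# ---- optimiser -------------------------------------------------------------

#' Adam update over every trainable parameter touched by a tape
#'
#' @param tp a tape on which [tp_backward()] has been run
#' @param lr learning rate
#' @param betas momentum coefficients
#' @param eps numerical stabiliser
#' @keywords internal
adam_step <- function(tp, lr = 1e-3, betas = c(0.9, 0.999), eps = 1e-8) {
  for (ref in tp$param_refs) {
    g <- tp$grads[[ref$id]]
    if (is.null(g)) next
    mod <- ref$mod
    pn <- ref$pname
    st <- mod$opt[[pn]]
    if (is.null(st)) st <- list(m = 0 * g, v = 0 * g, t = 0L)
    st$t <- st$t + 1L
    st$m <- betas[1] * st$m + (1 - betas[1]) * g
    st$v <- betas[2] * st$v + (1 - betas[2]) * g * g
    mhat <- st$m / (1 - betas[1]^st$t)
    vhat <- st$v / (1 - betas[2]^st$t)
    mod$params[[pn]] <- mod$params[[pn]] - lr * mhat / (sqrt(vhat) + eps)
    mod$opt[[pn]] <- st
  }
  invisible(NULL)
}
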