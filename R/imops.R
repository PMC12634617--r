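# Raster primitives shared across modules: separable Gaussian filtering,
# generic small-kernel convolution with reflective borders, affine warps and
# resampling, and RGB<->HSV conversion.  Grayscale rasters are H x W numeric
# matrices; colour images are H x W x 3 arrays on a 0..255 scale.

reflect_index <- function(i, n) {
  # reflect-101 style without repeating the edge sample twice
  i <- ((i - 1) %% (2 * n)) + 1
  ifelse(i > n, 2 * n + 1 - i, i)
}

pad_reflect <- function(x, r) {
  H <- nrow(x); W <- ncol(x)
  ri <- reflect_index(seq(1 - r, H + r), H)
  ci <- reflect_index(seq(1 - r, W + r), W)
  x[ri, ci, drop = FALSE]
}

gauss_kernel1d <- function(sigma, radius = ceiling(6 * sigma)) {
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian blur with reflective borders
#' @param x numeric matrix
#' @param sigma Gaussian standard deviation in pixels
#' @return blurred matrix of the same size
#' @keywords internal
gaussian_blur <- function(x, sigma) {
  stopifnot(sigma > 0)
  k <- gauss_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  H <- nrow(x); W <- ncol(x)
  xp <- pad_reflect(x, r)
  tmp <- matrix(0, H, W + 2L * r)
  for (t in seq_along(k)) tmp <- tmp + k[t] * xp[(t - 1L) + seq_len(H), , drop = FALSE]
  out <- matrix(0, H, W)
  for (t in seq_along(k)) out <- out + k[t] * tmp[, (t - 1L) + seq_len(W), drop = FALSE]
  out
}

# Convolution with an arbitrary small kernel (correlation; kernels used here
# are symmetric under 180-degree rotation, so the distinction is moot).
conv2d_same <- function(x, kern, boundary = c("reflect", "zero")) {
  boundary <- match.arg(boundary)
  kh <- nrow(kern); kw <- ncol(kern)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  r <- max(kh, kw) %/% 2L
  H <- nrow(x); W <- ncol(x)
  xp <- if (boundary == "reflect") pad_reflect(x, r) else {
    z <- matrix(0, H + 2L * r, W + 2L * r)
    z[r + seq_len(H), r + seq_len(W)] <- x
    z
  }
  out <- matrix(0, H, W)
  oh <- r - kh %/% 2L
  ow <- r - kw %/% 2L
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    kv <- kern[i, j]
    if (kv == 0) next
    out <- out + kv * xp[oh + i - 1L + seq_len(H), ow + j - 1L + seq_len(W), drop = FALSE]
  }
  out
}

box_counts <- function(ind, radius) {
  k <- matrix(1, 2L * radius + 1L, 2L * radius + 1L)
  conv2d_same(ind, k, boundary = "reflect")
}

#' Rotate an image about its centre keeping the original frame
#'
#' Inverse-maps output pixels through a rotation about the image centre;
#' out-of-frame samples take `fill`. Bilinear interpolation for photographs,
#' nearest-neighbour for masks.
#' @param img H x W matrix or H x W x C array
#' @param degrees counter-clockwise rotation angle
#' @param interp "bilinear" or "nearest"
#' @param fill fill value (scalar or length-C)
#' @return array of the same shape
#' @keywords internal
warp_rotate <- function(img, degrees, interp = c("bilinear", "nearest"),
                        fill = 0) {
  interp <- match.arg(interp)
  d <- dim(img)
  H <- d[1]; W <- d[2]; C <- if (length(d) == 3) d[3] else 1L
  th <- degrees * pi / 180
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  gy <- rep(seq_len(H) - 1, times = W) - cy
  gx <- rep(seq_len(W) - 1, each = H) - cx
  sy <- -sin(th) * gx + cos(th) * gy + cy
  sx <- cos(th) * gx + sin(th) * gy + cx
  out <- array(0, c(H, W, C))
  fill <- rep(fill, length.out = C)
  if (interp == "nearest") {
    ry <- round(sy); rx <- round(sx)
    ok <- ry >= 0 & ry < H & rx >= 0 & rx < W
    idx <- (pmin(pmax(rx, 0), W - 1)) * H + pmin(pmax(ry, 0), H - 1) + 1
    for (c in seq_len(C)) {
      ch <- if (length(d) == 3) img[, , c] else img
      v <- ch[idx]
      v[!ok] <- fill[c]
      out[, , c] <- v
    }
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    ty <- sy - y0; tx <- sx - x0
    ok <- sy >= 0 & sy <= H - 1 & sx >= 0 & sx <= W - 1
    cl <- function(v, n) pmin(pmax(v, 0), n - 1)
    i00 <- cl(x0, W) * H + cl(y0, H) + 1
    i01 <- cl(x0 + 1, W) * H + cl(y0, H) + 1
    i10 <- cl(x0, W) * H + cl(y0 + 1, H) + 1
    i11 <- cl(x0 + 1, W) * H + cl(y0 + 1, H) + 1
    for (c in seq_len(C)) {
      ch <- if (length(d) == 3) img[, , c] else img
      v <- (1 - ty) * ((1 - tx) * ch[i00] + tx * ch[i01]) +
           ty * ((1 - tx) * ch[i10] + tx * ch[i11])
      v[!ok] <- fill[c]
      out[, , c] <- v
    }
  }
  if (length(d) == 2) out[, , 1] else out
}

resample_matrix <- function(n_out, n_in, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  A <- matrix(0, n_out, n_in)
  sc <- n_in / n_out
  for (i in seq_len(n_out)) {
    s <- (i - 0.5) * sc - 0.5
    if (interp == "nearest") {
      j <- min(max(round(s), 0), n_in - 1)
      A[i, j + 1] <- 1
    } else {
      f <- floor(s); t <- s - f
      j0 <- min(max(f, 0), n_in - 1)
      j1 <- min(max(f + 1, 0), n_in - 1)
      A[i, j0 + 1] <- A[i, j0 + 1] + (1 - t)
      A[i, j1 + 1] <- A[i, j1 + 1] + t
    }
  }
  A
}

#' Resize an image or mask
#' @param img matrix or H x W x C array
#' @param h_out,w_out output size
#' @param interp "bilinear" or "nearest"
#' @return resized array
#' @keywords internal
resize_img <- function(img, h_out, w_out, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  d <- dim(img)
  C <- if (length(d) == 3) d[3] else 1L
  Ah <- resample_matrix(h_out, d[1], interp)
  Aw <- resample_matrix(w_out, d[2], interp)
  out <- array(0, c(h_out, w_out, C))
  for (c in seq_len(C)) {
    ch <- if (length(d) == 3) img[, , c] else img
    out[, , c] <- Ah %*% ch %*% t(Aw)
  }
  if (length(d) == 2) out[, , 1] else out
}

rgb2hsv_arr <- function(img) {
  d <- dim(img)
  m <- grDevices::rgb2hsv(t(matrix(img, ncol = 3)), maxColorValue = 255)
  array(t(m), c(d[1], d[2], 3))
}

hsv2rgb_arr <- function(hsv) {
  d <- dim(hsv)
  h <- pmin(pmax(as.vector(hsv[, , 1]), 0), 1) * 6
  s <- pmin(pmax(as.vector(hsv[, , 2]), 0), 1)
  v <- pmin(pmax(as.vector(hsv[, , 3]), 0), 1)
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  array(c(r, g, b), c(d[1], d[2], 3)) * 255
}

luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

# Run code under a temporary RNG state derived from `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
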