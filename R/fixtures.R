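# Seeded synthetic stick scenes with exact ground truth.  The generator
# emulates the acquisition conditions the pipeline targets -- a stick-shaped
# foreground on a red or green backdrop, beige substrate texture, soft-edged
# brown browning patches, optional plastic-bag glare, and low/normal/over
# exposure -- without claiming photorealism.

EXPOSURE_GAINS <- c(low = 0.8, normal = 1.0, over = 1.25)
STAGE_BANDS <- list(pre = c(0, 0.10), mid = c(0.30, 0.60), post = c(0.70, 1))

#' Scene specification for the synthetic generator
#'
#' @param seed integer seed; scenes are bit-identical under it
#' @param canvas c(H, W), at least 64 x 64
#' @param background backdrop colour, "red" or "green"
#' @param exposure "low", "normal" or "over" (gains 0.8 / 1.0 / 1.25)
#' @param stage maturity stage; defaults to the band containing
#'   `nominal_browning_ratio`
#' @param nominal_browning_ratio target browning fraction of the stick area
#' @param n_blobs initial number of browning patches
#' @param blob_softness edge-gradient width in pixels
#' @param bag_glare add specular plastic-bag streaks
#' @return a `scene_spec`
#' @export
scene_spec <- function(seed = 0L, canvas = c(96L, 96L),
                       background = c("red", "green"),
                       exposure = c("normal", "low", "over"),
                       stage = NULL, nominal_browning_ratio = 0.45,
                       n_blobs = 6L, blob_softness = 3, bag_glare = FALSE) {
  background <- match.arg(background)
  exposure <- match.arg(exposure)
  stopifnot(canvas[1] >= 64, canvas[2] >= 64,
            nominal_browning_ratio >= 0, nominal_browning_ratio <= 1)
  if (is.null(stage)) {
    stage <- if (nominal_browning_ratio < 0.10) "pre"
             else if (nominal_browning_ratio <= 0.60 && nominal_browning_ratio >= 0.30) "mid"
             else if (nominal_browning_ratio > 0.70) "post"
             else "unknown"
  }
  structure(list(seed = as.integer(seed), canvas = as.integer(canvas),
                 background = background, exposure = exposure, stage = stage,
                 nominal_browning_ratio = nominal_browning_ratio,
                 n_blobs = as.integer(n_blobs), blob_softness = blob_softness,
                 bag_glare = bag_glare),
            class = "scene_spec")
}

rounded_rect_dist <- function(H, W, cy, cx, hh, hw, r) {
  gy <- rep(seq_len(H) - 1, times = W)
  gx <- rep(seq_len(W) - 1, each = H)
  dx <- pmax(abs(gx - cx) - (hw - r), 0)
  dy <- pmax(abs(gy - cy) - (hh - r), 0)
  matrix(sqrt(dx^2 + dy^2) - r, H, W)
}

band_noise <- function(H, W, sigma) {
  gaussian_blur(matrix(stats::rnorm(H * W), H, W), sigma)
}

#' Render one synthetic stick scene
#'
#' Draws a rounded-rectangle stick silhouette with banded substrate texture,
#' places soft-edged browning blobs until the achieved browning ratio lies
#' within +-0.02 of the nominal target (the last blob's radius is tuned by
#' bisection), then applies the exposure gain and optional glare streaks.
#' Fully deterministic under the spec's seed.
#'
#' @param spec a `scene_spec`
#' @return a `scene_bundle`: list with `image` (`stick_image`), `contour`
#'   (`polygon_annotation`), `stick_mask`, `browning_mask` (binary
#'   `mask_raster`s) and `achieved_ratio`
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    H <- spec$canvas[1]; W <- spec$canvas[2]
    id <- sprintf("scene_%s_%d", spec$stage, spec$seed)
    cy <- (H - 1) / 2; cx <- (W - 1) / 2
    hh <- 0.30 * H * stats::runif(1, 0.9, 1.1)
    hw <- 0.38 * W * stats::runif(1, 0.9, 1.1)
    r <- 0.45 * min(hh, hw)
    sd_stick <- rounded_rect_dist(H, W, cy, cx, hh, hw, r)
    stick <- (sd_stick <= 0) * 1
    n_stick <- sum(stick)

    # browning blobs: distance field of the union, tuned to the target ratio
    target <- spec$nominal_browning_ratio
    dmin <- matrix(Inf, H, W)
    ratio_of <- function(dm) sum((dm <= 0) & (stick > 0)) / n_stick
    if (target > 0) {
      blob_dist <- function(cyb, cxb, rad) {
        gy <- rep(seq_len(H) - 1, times = W)
        gx <- rep(seq_len(W) - 1, each = H)
        el <- stats::runif(1, 0.7, 1.4)   # mild anisotropy
        matrix(sqrt(((gy - cyb) * el)^2 + ((gx - cxb) / el)^2) - rad, H, W)
      }
      inside <- which(stick > 0)
      attempts <- 0L
      repeat {
        attempts <- attempts + 1L
        if (attempts > 300L) {
          stop(sprintf("could not reach browning ratio %.3f; best achieved %.3f",
                       target, ratio_of(dmin)))
        }
        px <- inside[sample.int(length(inside), 1L)]
        cyb <- (px - 1) %% H
        cxb <- (px - 1) %/% H
        rad <- stats::runif(1, 0.10, 0.22) * sqrt(n_stick / pi) *
          max(1, sqrt(3 * target))
        cand <- pmin(dmin, blob_dist(cyb, cxb, rad))
        if (ratio_of(cand) < target - 0.01) {
          dmin <- cand
          next
        }
        # bisection on the last blob's radius to land inside the band
        lo <- 0; hi <- rad
        for (it in 1:40) {
          mid <- (lo + hi) / 2
          cand <- pmin(dmin, blob_dist(cyb, cxb, mid))
          if (ratio_of(cand) < target) lo <- mid else hi <- mid
        }
        cand <- pmin(dmin, blob_dist(cyb, cxb, hi))
        if (abs(ratio_of(cand) - target) <= 0.02) {
          dmin <- cand
          break
        }
        # a coarse stick raster can make the target unreachable from below
        # with this blob; accept the enlarged field and continue
        dmin <- pmin(dmin, blob_dist(cyb, cxb, lo))
        if (abs(ratio_of(dmin) - target) <= 0.02) break
      }
    }
    browning <- ((dmin <= 0) & (stick > 0)) * 1
    achieved <- if (target > 0) sum(browning) / n_stick else 0

    # ---- render ----
    bg <- if (spec$background == "red") c(178, 34, 34) else c(34, 120, 34)
    substrate <- c(214, 189, 148)
    brown <- c(96, 52, 26)
    img <- array(0, c(H, W, 3))
    tex <- band_noise(H, W, 2.5)
    tex <- tex / max(abs(tex), 1e-9)
    alpha_b <- pmin(pmax(0.5 - dmin / spec$blob_softness, 0), 1)
    depth <- stats::runif(length(alpha_b), 0.85, 1)   # per-pixel pigment depth
    for (c in 1:3) {
      base <- substrate[c] + 18 * tex
      mixed <- base * (1 - alpha_b * depth) + brown[c] * alpha_b * depth
      img[, , c] <- ifelse(stick > 0, mixed, bg[c] + 6 * tex)
    }
    if (spec$bag_glare) {
      gy <- rep(seq_len(H) - 1, times = W)
      gx <- rep(seq_len(W) - 1, each = H)
      for (s in 1:2) {
        off <- stats::runif(1, -0.3, 0.3) * W
        dstreak <- abs(gx - gy - off) / sqrt(2)
        glare <- matrix(exp(-(dstreak / 2.5)^2), H, W) * 0.6
        for (c in 1:3) img[, , c] <- img[, , c] * (1 - glare * stick) +
            255 * glare * stick
      }
    }
    img <- clamp255(img * EXPOSURE_GAINS[[spec$exposure]])
    stick_m <- mask_raster(id, stick, "binary")
    bundle <- list(image = stick_image(id, img, spec$stage, spec$background,
                                       spec$exposure),
                   contour = mask_to_polygons(stick_m, spec$stage),
                   stick_mask = stick_m,
                   browning_mask = mask_raster(id, browning, "binary"),
                   achieved_ratio = achieved,
                   spec = spec)
    class(bundle) <- "scene_bundle"
    bundle
  })
}

#' Generate a corpus of synthetic scenes
#'
#' Stages are drawn from `stage_mix`; per-scene seeds derive from the corpus
#' seed. When `out_dir` is given the corpus is also written in the on-disk
#' layout the pipeline consumes: `images/` (PNG), `labels_contour/` (Labelme
#' JSON), `masks_browning/`, `masks_stick/` (PNG) and `manifest.csv`.
#'
#' @param n number of scenes (> 0)
#' @param seed corpus seed
#' @param stage_mix probabilities for (pre, mid, post); must sum to 1
#' @param canvas scene canvas size
#' @param out_dir optional output directory
#' @param ... further fields forwarded to [scene_spec()]
#' @return list of `scene_bundle`s
#' @export
generate_corpus <- function(n, seed = 0L, stage_mix = c(0.2, 0.55, 0.25),
                            canvas = c(96L, 96L), out_dir = NULL, ...) {
  if (n <= 0) stop("n must be positive")
  if (abs(sum(stage_mix) - 1) > 1e-9) stop("stage_mix must sum to 1")
  stages <- with_seed(seed,
    sample(STAGES, n, replace = TRUE, prob = stage_mix))
  ratios <- with_seed(seed + 1L, vapply(stages, function(s) {
    b <- STAGE_BANDS[[s]]
    stats::runif(1, b[1] + 0.02, min(b[2], 0.88) - 0.02)
  }, 0))
  bundles <- lapply(seq_len(n), function(i) {
    sp <- scene_spec(seed = seed * 1000L + i, canvas = canvas,
                     background = if (i %% 2 == 0) "green" else "red",
                     stage = stages[i], nominal_browning_ratio = ratios[i], ...)
    b <- generate_scene(sp)
    b$image$id <- sprintf("scene_%03d_%s", i, stages[i])
    for (f in c("contour", "stick_mask", "browning_mask"))
      b[[f]]$image_id <- b$image$id
    b
  })
  if (!is.null(out_dir)) write_corpus(bundles, out_dir)
  bundles
}

#' Write a corpus in the on-disk pipeline layout
#' @param bundles list of `scene_bundle`s
#' @param out_dir output directory
#' @return `out_dir`, invisibly
#' @export
write_corpus <- function(bundles, out_dir) {
  for (d in c("images", "labels_contour", "masks_browning", "masks_stick"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(bundles, function(b) {
    id <- b$image$id
    write_stick_image(b$image, file.path(out_dir, "images", paste0(id, ".png")))
    write_labelme(b$contour, file.path(out_dir, "labels_contour", paste0(id, ".json")))
    write_mask_png(b$browning_mask, file.path(out_dir, "masks_browning", paste0(id, ".png")))
    write_mask_png(b$stick_mask, file.path(out_dir, "masks_stick", paste0(id, ".png")))
    data.frame(id = id, stage = b$image$stage, background = b$image$background,
               exposure = b$image$exposure_tag, achieved_ratio = b$achieved_ratio)
  })
  utils::write.csv(do.call(rbind, rows), file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
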