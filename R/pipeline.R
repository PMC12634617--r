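# End-to-end orchestration: contour detection -> ROI extraction -> browning
# segmentation -> browning report, plus training entry points for both
# stages.

#' Pipeline configuration
#'
#' @param stage1 a [contour_model_config()]
#' @param stage2 an [rsunet_config()]
#' @param stage2_input c(H, W) input size of the browning net (multiples of
#'   32); the ROI crop is letterboxed to it
#' @param confidence,nms_iou,mask_binarize inference thresholds
#' @param seed integer seed recorded in every report
#' @return a `pipeline_config`
#' @export
pipeline_config <- function(stage1 = contour_model_config(),
                            stage2 = rsunet_config(),
                            stage2_input = c(1024L, 448L),
                            confidence = 0.25, nms_iou = 0.7,
                            mask_binarize = 0.5, seed = 0L) {
  stopifnot(all(stage2_input %% 32 == 0))
  structure(list(stage1 = stage1, stage2 = stage2,
                 stage2_input = as.integer(stage2_input),
                 confidence = confidence, nms_iou = nms_iou,
                 mask_binarize = mask_binarize, seed = as.integer(seed)),
            class = "pipeline_config")
}

roi_to_stage2_input <- function(roi, input_size) {
  lb <- letterbox_resize(roi$image$pixels, input_size, fill = 0)
  list(x = lb$img / 255, lb = lb)
}

stage2_mask_to_roi <- function(prob, lb) {
  nh <- round(lb$src[1] * lb$scale); nw <- round(lb$src[2] * lb$scale)
  crop <- prob[lb$pad[1] + seq_len(nh), lb$pad[2] + seq_len(nw), drop = FALSE]
  resize_img(crop, lb$src[1], lb$src[2], "bilinear")
}

#' Run the two-stage browning quantification pipeline
#'
#' For every image: predict stick instances, keep the highest-confidence one,
#' extract its ROI, letterbox it to the stage-2 input size, segment browning
#' with the RS-UNet, map the mask back through the stored crop offset, and
#' report the browning area ratio, the stage-1 maturity class and a
#' pigmentation heatmap. Images with no instance above threshold yield a
#' report flagged `"no stick detected"`.
#'
#' @param stage1 materialised contour model
#' @param stage2 materialised RS-UNet
#' @param images list of `stick_image`s
#' @param config a [pipeline_config()] (its stage configs must match the
#'   models passed)
#' @return list of browning reports
#' @export
run_two_stage <- function(stage1, stage2, images, config = pipeline_config()) {
  if (!identical(config_hash(stage1$meta$config), config_hash(config$stage1)) ||
      !identical(config_hash(stage2$meta$config), config_hash(config$stage2)))
    stop("model configuration hash does not match the pipeline config; refusing to run")
  chash <- config_hash(config)
  lapply(images, function(img) {
    inst <- predict_instances(stage1, img, config$confidence, config$nms_iou)
    if (length(inst) == 0) {
      return(list(image_id = img$id, flag = "no stick detected",
                  stage = NA_character_, ratio_percent = NA_real_,
                  config_hash = chash, seed = config$seed))
    }
    top <- inst[[1]]
    roi <- extract_roi(img, top, config$mask_binarize)
    s2 <- roi_to_stage2_input(roi, config$stage2_input)
    prob <- rsunet_forward(stage2, array(s2$x, c(dim(s2$x)[1:2], 3, 1)))[, , 1, 1]
    roi_prob <- stage2_mask_to_roi(prob, s2$lb)
    bin <- (roi_prob >= config$mask_binarize) * roi$mask$values
    H <- dim(img$pixels)[1]; W <- dim(img$pixels)[2]
    browning_full <- matrix(0, H, W)
    rr <- roi$offset[1] + seq_len(nrow(bin))
    cc <- roi$offset[2] + seq_len(ncol(bin))
    browning_full[rr, cc] <- bin
    roi_full <- matrix(0, H, W)
    roi_full[rr, cc] <- roi$mask$values
    br <- browning_ratio(mask_raster(img$id, browning_full),
                         mask_raster(img$id, roi_full))
    heat <- pigment_heatmap(roi$image, mask_raster(img$id, bin))
    list(image_id = img$id, flag = "ok", stage = top$stage,
         confidence = top$confidence,
         roi_pixels = br$roi_pixels, browning_pixels = br$browning_pixels,
         ratio_percent = br$ratio_percent,
         heatmap = heat, roi_offset = roi$offset,
         config_hash = chash, seed = config$seed)
  })
}

#' Write browning reports as JSON and CSV
#' @param reports list returned by [run_two_stage()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_browning_reports <- function(reports, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slim <- lapply(reports, function(r) r[setdiff(names(r), "heatmap")])
  jsonlite::write_json(slim, file.path(dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  df <- do.call(rbind, lapply(slim, function(r)
    data.frame(image_id = r$image_id, flag = r$flag,
               stage = r$stage %||% NA,
               roi_pixels = r$roi_pixels %||% NA,
               browning_pixels = r$browning_pixels %||% NA,
               ratio_percent = r$ratio_percent %||% NA)))
  utils::write.csv(df, file.path(dir, "reports.csv"), row.names = FALSE)
  invisible(dir)
}

prepare_browning_batch <- function(bundles, input_size) {
  N <- length(bundles)
  xb <- array(0, c(input_size[1], input_size[2], 3, N))
  mb <- array(0, c(input_size[1], input_size[2], 1, N))
  for (i in seq_len(N)) {
    b <- bundles[[i]]
    roi <- extract_roi(b$image, b$stick_mask)
    s2 <- roi_to_stage2_input(roi, input_size)
    xb[, , , i] <- s2$x
    bm <- b$browning_mask$values[roi$offset[1] + seq_len(dim(roi$image$pixels)[1]),
                                 roi$offset[2] + seq_len(dim(roi$image$pixels)[2]),
                                 drop = FALSE]
    mlb <- letterbox_resize(array(rep(bm, 3), c(dim(bm), 3)), input_size, fill = 0)
    mb[, , 1, i] <- (mlb$img[, , 1] > 0.5) * 1
  }
  list(x = xb, masks = mb)
}

#' Train one pipeline stage on a scene corpus
#'
#' @param which "contour" (stage 1) or "browning" (stage 2)
#' @param bundles list of `scene_bundle`s (or a corpus directory written by
#'   [write_corpus()])
#' @param config a [pipeline_config()]
#' @param steps optimisation steps
#' @param lr learning rate (stage defaults: 1e-3 contour, 1e-4 browning at
#'   full scale; overfit runs use larger rates)
#' @param checkpoint optional path to write the trained checkpoint
#' @param seed RNG seed for initialisation and dropout
#' @param verbose print progress
#' @return list(model, log, checkpoint)
#' @export
train_stage <- function(which = c("contour", "browning"), bundles,
                        config = pipeline_config(), steps = 200L, lr = NULL,
                        checkpoint = NULL, seed = 0L, verbose = FALSE) {
  which <- match.arg(which)
  if (is.character(bundles)) bundles <- read_corpus(bundles)
  if (length(bundles) == 0) stop("empty corpus")
  set.seed(seed)
  if (which == "contour") {
    model <- assemble_contour_model(config$stage1)
    nn_materialize(model)
    log <- train_contour(model, bundles, steps = steps, lr = lr %||% 2e-3,
                         verbose = verbose)
  } else {
    model <- assemble_rsunet(config$stage2)
    nn_materialize(model)
    batch <- prepare_browning_batch(bundles, config$stage2_input)
    log <- train_rsunet(model, batch$x, batch$masks, steps = steps,
                        lr = lr %||% 2e-3, verbose = verbose)
  }
  if (!is.null(checkpoint)) {
    save_checkpoint(model, checkpoint)
    utils::write.csv(log, paste0(tools::file_path_sans_ext(checkpoint),
                                 "_log.csv"), row.names = FALSE)
  }
  list(model = model, log = log, checkpoint = checkpoint)
}

#' Read a corpus directory back into scene bundles
#'
#' Reads the layout written by [write_corpus()] through the standard parsers
#' (PNG images and masks, Labelme contour JSON).
#' @param dir corpus directory
#' @return list of `scene_bundle`-like records
#' @export
read_corpus <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         colClasses = c(id = "character"))
  lapply(seq_len(nrow(man)), function(i) {
    id <- man$id[i]
    img <- read_stick_image(file.path(dir, "images", paste0(id, ".png")),
                            id = id, stage = man$stage[i],
                            background = man$background[i],
                            exposure_tag = man$exposure[i])
    contour <- parse_polygon_annotation(file.path(dir, "labels_contour",
                                                  paste0(id, ".json")))
    contour$image_id <- id
    d <- dim(img$pixels)
    structure(list(image = img, contour = contour,
                   stick_mask = polygon_to_mask(contour, d[1], d[2]),
                   browning_mask = read_mask_png(
                     file.path(dir, "masks_browning", paste0(id, ".png")), id),
                   achieved_ratio = man$achieved_ratio[i]),
              class = "scene_bundle")
  })
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys `stage1`, `stage2` and the threshold fields mirror the
#' arguments of [pipeline_config()], [contour_model_config()] and
#' [rsunet_config()].
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  s1 <- do.call(contour_model_config, y$stage1 %||% list())
  s2 <- do.call(rsunet_config, y$stage2 %||% list())
  pipeline_config(stage1 = s1, stage2 = s2,
                  stage2_input = unlist(y$stage2_input %||% c(1024L, 448L)),
                  confidence = y$confidence %||% 0.25,
                  nms_iou = y$nms_iou %||% 0.7,
                  mask_binarize = y$mask_binarize %||% 0.5,
                  seed = y$seed %||% 0L)
}
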