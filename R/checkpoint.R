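# Checkpointing: module state is collected in tree order and stored together
# with the builder configuration and its hash, so weights can only be loaded
# into an identically configured model.

collect_state <- function(mod) {
  list(params = mod$params, buffers = mod$buffers,
       children = lapply(mod$children, collect_state))
}

restore_state <- function(mod, st) {
  if (!is.null(st$params)) mod$params <- st$params
  if (length(st$buffers)) mod$buffers <- st$buffers
  if (length(mod$children) != length(st$children))
    stop("checkpoint structure does not match the model")
  for (i in seq_along(mod$children)) restore_state(mod$children[[i]], st$children[[i]])
  invisible(mod)
}

rec_unclass <- function(x) {
  x <- unclass(x)
  if (is.list(x)) x <- lapply(x, rec_unclass)
  x
}

config_hash <- function(config) {
  f <- tempfile()
  writeLines(as.character(jsonlite::toJSON(rec_unclass(config),
                                           auto_unbox = TRUE, digits = NA)), f)
  h <- unname(tools::md5sum(f))
  unlink(f)
  h
}

save_checkpoint_obj <- function(model) {
  cfg <- model$meta$config
  list(kind = model$kind, config = cfg,
       config_hash = if (!is.null(cfg)) config_hash(cfg) else NA_character_,
       state = collect_state(model))
}

#' Save a model checkpoint
#'
#' The checkpoint embeds the builder configuration and its hash; loading
#' refuses a model assembled under a different configuration.
#' @param model an assembled model
#' @param path RDS file
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(save_checkpoint_obj(model), path)
  invisible(path)
}

#' Load a checkpoint into an assembled model
#' @param model an assembled model of the matching configuration
#' @param path RDS file written by [save_checkpoint()]
#' @return the model with restored weights, invisibly
#' @export
load_checkpoint <- function(model, path) {
  obj <- readRDS(path)
  if (!identical(obj$config_hash, config_hash(model$meta$config)))
    stop("checkpoint was written under a different model configuration ",
         "(hash mismatch); refusing to load")
  restore_state(model, obj$state)
  invisible(model)
}
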