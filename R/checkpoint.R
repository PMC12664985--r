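#' Save a trained model to a single JSON checkpoint
#'
#' The checkpoint bundles the architecture configuration, vocabulary, mode,
#' and all weights in plain JSON (full double precision), so it survives any
#' text-only transport.
#'
#' @param model A `pt_model` or `pt_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  model <- as_pt_model(model)
  payload <- list(
    format = "proteotag-checkpoint-v1",
    config = unclass(model$config),
    vocab = list(classes = model$vocab$classes,
                 tags = unname(model$vocab$tag_map)),
    mode = model$mode,
    pad_to = model$pad_to,
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p)) else list(data = p)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model from a JSON checkpoint
#'
#' @param path Checkpoint written by [save_model()].
#' @return A `pt_model`.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "proteotag-checkpoint-v1"))
    abort("not a proteotag checkpoint")
  cfg <- do.call(model_config, payload$config)
  vocab <- aa_vocabulary(payload$vocab$classes, payload$vocab$tags)
  params <- lapply(payload$params, function(p) {
    if (!is.null(p$dim)) matrix(p$data, p$dim[1], p$dim[2]) else p$data
  })
  structure(list(params = params, config = cfg, vocab = vocab,
                 classes = vocab$classes, tag_map = vocab$tag_map,
                 mode = payload$mode,
                 pad_to = payload$pad_to),
            class = "pt_model")
}
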