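#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training log of a fitted model
#'
#' @param x A `pt_fit`.
#' @param ... Unused.
#' @return Tibble: `step`, `lr`, `train_loss`, `eval_loss`, `eval_macro_f1`.
#' @export
tidy.pt_fit <- function(x, ...) x$log

#' One-row summary of a fitted model
#'
#' @param x A `pt_fit`.
#' @param ... Unused.
#' @return Tibble with `n_parameters`, `n_layers`, `d_model`, `best_step`,
#'   `best_eval_macro_f1`, `final_train_loss`.
#' @export
glance.pt_fit <- function(x, ...) {
  tibble::tibble(
    n_parameters = sum(vapply(x$model$params, length, integer(1))),
    n_layers = x$config$n_layers,
    d_model = x$config$d_model,
    best_step = x$best_step,
    best_eval_macro_f1 = x$best_metric,
    final_train_loss = utils::tail(x$log$train_loss, 1)
  )
}

#' Per-class metric table
#'
#' @param x A `tag_metrics` object from [compute_metrics()].
#' @param ... Unused.
#' @return Tibble with one row per class.
#' @export
tidy.tag_metrics <- function(x, ...) x$per_class

#' One-row metric summary
#'
#' @param x A `tag_metrics` object.
#' @param ... Unused.
#' @return Tibble with `accuracy`, `macro_f1`, `weighted_f1`, `n`,
#'   `n_unknown`.
#' @export
glance.tag_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_f1 = x$macro_f1,
                 weighted_f1 = x$weighted_f1, n = x$n, n_unknown = x$n_unknown)
}

#' Coordinates of a single-layer projection
#'
#' @param x A `layer_projection`.
#' @param ... Unused.
#' @return Tibble: `layer`, `position`, `residue`, `z1`, `z2`.
#' @export
tidy.layer_projection <- function(x, ...) {
  tibble::tibble(layer = x$layer, position = seq_len(nrow(x$coords)),
                 residue = x$residues %||% NA_character_,
                 z1 = x$coords[, 1], z2 = x$coords[, 2])
}

#' Long table of all layer projections
#'
#' @param x A `helix_projection` from [project_all_layers()].
#' @param ... Unused.
#' @return Tibble: `layer`, `position`, `residue`, `z1`, `z2`.
#' @export
tidy.helix_projection <- function(x, ...) {
  dplyr::bind_rows(lapply(x$projections, tidy))
}

#' Per-position profile of a windowed attribution
#'
#' @param x A `windowed_attribution` from [deeplift_windowed()].
#' @param ... Unused.
#' @return Tibble: `position`, `residue`, `score`, `n_windows`.
#' @export
tidy.windowed_attribution <- function(x, ...) x$profile

#' @importFrom rlang %||%
NULL
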