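#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Training curve of a fitted model
#'
#' Training loss per logged step, with eval macro F1 overlaid where
#' available.
#'
#' @param object A `pt_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pt_fit <- function(object, ...) {
  log <- object$log
  p <- ggplot2::ggplot(log, ggplot2::aes(x = .data$step, y = .data$train_loss)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "step", y = "train loss (nats/token)")
  ev <- log[!is.na(log$eval_macro_f1), ]
  if (nrow(ev)) {
    p <- p + ggplot2::geom_point(
      data = ev, ggplot2::aes(y = .data$eval_macro_f1 * max(log$train_loss)),
      colour = "steelblue") +
      ggplot2::scale_y_continuous(
        sec.axis = ggplot2::sec_axis(~ . / max(log$train_loss),
                                     name = "eval macro F1"))
  }
  p
}

#' Per-residue attribution profile
#'
#' @param object A `pt_attribution` tibble (from [shap_like()] or
#'   [integrated_gradients()]) or a `windowed_attribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pt_attribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$score > 0), show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "seagreen", `FALSE` = "firebrick")) +
    ggplot2::labs(x = "position", y = "attribution",
                  title = attr(object, "method"))
}

#' @rdname autoplot.pt_attribution
#' @export
autoplot.windowed_attribution <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position", y = "attribution",
                  title = sprintf("windowed attribution (w=%d, stride=%d)",
                                  object$window, object$stride))
}

#' Influence profile with its peak threshold
#'
#' @param object An `influence_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.influence_profile <- function(object, ...) {
  df <- tibble::tibble(position = seq_along(object$avg_influence),
                       influence = object$avg_influence)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$influence)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "position", y = "normalized influence")
}

#' Layer-wise projection panels
#'
#' One panel per layer, points coloured by residue identity, visualizing how
#' residue features separate with depth.
#'
#' @param object A `helix_projection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.helix_projection <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z1, y = .data$z2,
                                   colour = .data$residue)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~layer, scales = "free") +
    ggplot2::labs(x = "first singular axis", y = "second singular axis")
}
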