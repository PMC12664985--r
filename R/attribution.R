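# Forward from explicit token embeddings (positions added internally) and
# return the target-tag output plus its gradient w.r.t. those embeddings.
# target = "logit" differentiates the pre-softmax tag logit at the last
# position; "nll" differentiates the negative log-likelihood of the tag.
grad_wrt_embeddings <- function(model, Etok, tag_id, target = "logit") {
  cfg <- model$config
  T <- nrow(Etok)
  if (T > cfg$context_length) abort("sequence exceeds model context")
  X <- Etok + model$params$pos[seq_len(T), , drop = FALSE]
  fw <- pt_forward_core(model$params, cfg, X, 1L, T, keep_cache = TRUE)
  dlog <- fw$logits * 0
  if (target == "logit") {
    val <- fw$logits[T, tag_id]
    dlog[T, tag_id] <- 1
  } else {
    p <- softmax_rows(fw$logits[T, , drop = FALSE])[1, ]
    val <- -log(max(p[tag_id], 1e-12))
    dlog[T, ] <- p
    dlog[T, tag_id] <- p[tag_id] - 1
  }
  bw <- pt_backward_core(model$params, cfg, fw, dlog)
  list(value = val, grad = bw$dX)
}

resolve_tag <- function(model, target_tag) {
  i <- match(target_tag, model$classes)
  if (is.na(i)) i <- match(target_tag, unname(model$tag_map))
  if (is.na(i)) abort(paste0("unknown target tag/class: ", target_tag))
  list(id = tag_ids(model$vocab)[i], class = model$classes[i])
}

attribution_tibble <- function(sequence, scores, method, target, baseline_id = NA) {
  out <- tibble::tibble(position = seq_len(nchar(sequence)),
                        residue = chars(sequence), score = scores)
  structure(out, method = method, target = target, baseline_id = baseline_id,
            class = c("pt_attribution", class(out)))
}

#' Gradient-times-embedding per-residue attribution
#'
#' Computes phi_i = sum_j G_ij * E(x)_ij, the dot product of the gradient of
#' the target-tag output with the token's input embedding — the fast,
#' SHAP-flavoured saliency used to designate each residue's influence toward
#' a class decision. On an additive (0-layer, linear-head) surrogate these
#' values coincide with exact Shapley values against a zero-embedding
#' baseline (see [exhaustive_shapley()]).
#'
#' @param model A `pt_model` or `pt_fit`.
#' @param sequence Amino-acid string (non-empty).
#' @param target_tag Class label (or tag character) to attribute toward.
#' @param target `"logit"` (default) differentiates the pre-softmax tag
#'   logit; `"nll"` the tag's negative log-likelihood.
#' @return A `pt_attribution` tibble: `position`, `residue`, `score`.
#' @export
shap_like <- function(model, sequence, target_tag, target = c("logit", "nll")) {
  model <- as_pt_model(model)
  target <- match.arg(target)
  if (!nzchar(sequence)) abort("empty sequence")
  tg <- resolve_tag(model, target_tag)
  ids <- encode_text(build_prompt(model, sequence), model$vocab)
  Etok <- model$params$tok[ids, , drop = FALSE]
  gr <- grad_wrt_embeddings(model, Etok, tg$id, target)
  phi <- rowSums(gr$grad * Etok)[seq_len(nchar(sequence))]
  attribution_tibble(sequence, phi, "shap_like", tg$class)
}

#' Integrated gradients from a reference embedding
#'
#' Path-integral attribution: IG_i = (x_i - x0_i) . integral over alpha of
#' dF/dx_i along the straight path from the reference embedding x0 to the
#' input x, with F the pre-softmax logit of the target tag. The integral is
#' approximated by the midpoint rule with `steps` points, so attributions
#' sum to F(x) - F(x0) (completeness) up to quadrature error that shrinks
#' with `steps`; for a linear F the result is exact at any step count.
#'
#' @inheritParams shap_like
#' @param steps Number of integration steps (default 50).
#' @param baseline `"pad"` (default): the pad token's embedding at every
#'   position, the all-padding reference; or `"zero"` for the zero vector.
#' @return A `pt_attribution` tibble with attributes `f_input`, `f_baseline`
#'   (target outputs at the endpoints, for completeness checks).
#' @export
integrated_gradients <- function(model, sequence, target_tag, steps = 50L,
                                 baseline = c("pad", "zero")) {
  model <- as_pt_model(model)
  baseline <- match.arg(baseline)
  if (steps < 1) abort("`steps` must be >= 1")
  if (!nzchar(sequence)) abort("empty sequence")
  tg <- resolve_tag(model, target_tag)
  ids <- encode_text(build_prompt(model, sequence), model$vocab)
  E1 <- model$params$tok[ids, , drop = FALSE]
  E0 <- if (baseline == "pad") {
    matrix(model$params$tok[pad_id(model$vocab), ], nrow(E1), ncol(E1), byrow = TRUE)
  } else {
    E1 * 0
  }
  gsum <- E1 * 0
  for (k in seq_len(steps)) {
    alpha <- (k - 0.5) / steps
    gsum <- gsum + grad_wrt_embeddings(model, E0 + alpha * (E1 - E0), tg$id)$grad
  }
  ig <- rowSums((E1 - E0) * gsum / steps)[seq_len(nchar(sequence))]
  out <- attribution_tibble(sequence, ig, "integrated_gradients", tg$class,
                            baseline_id = baseline)
  attr(out, "f_input") <- grad_wrt_embeddings(model, E1, tg$id)$value
  attr(out, "f_baseline") <- grad_wrt_embeddings(model, E0, tg$id)$value
  out
}

#' Sliding-window spans with overlap
#'
#' Windows start at 0 and advance by `stride`, so consecutive spans share
#' `window - stride` positions (window 1: 0-31, window 2: 16-47 at the
#' defaults); a final truncated span is appended whenever trailing residues
#' would otherwise be uncovered. Coordinates are 0-based inclusive.
#'
#' @param seq_len Sequence length in residues.
#' @param window Window size (default 32).
#' @param stride Step between window starts (default 16; `1 <= stride <=
#'   window`).
#' @return Tibble: `index`, `start`, `end` (0-based inclusive).
#' @export
window_spans <- function(seq_len, window = 32L, stride = 16L) {
  if (window < 1) abort("`window` must be >= 1")
  if (stride < 1 || stride > window) abort("`stride` must be in [1, window]")
  if (seq_len == 0)
    return(tibble::tibble(index = integer(), start = integer(), end = integer()))
  starts <- seq(0L, by = as.integer(stride),
                length.out = max(0L, (seq_len - window) %/% stride + 1L))
  if (seq_len < window) starts <- integer(0)
  ends <- starts + window - 1L
  covered <- if (length(ends)) max(ends) else -1L
  if (covered < seq_len - 1L) {
    nxt <- if (length(starts)) starts[length(starts)] + stride else 0L
    starts <- c(starts, nxt)
    ends <- c(ends, seq_len - 1L)
  }
  tibble::tibble(index = seq_along(starts), start = as.integer(starts),
                 end = as.integer(ends))
}

#' Reference-based windowed attribution profile
#'
#' Attributes each sliding window independently against the reference
#' embedding (the all-padding baseline by default): the window is encoded as
#' its own prompt, per-residue attributions are computed as the path
#' integral of gradients from reference to input (so each window's
#' attribution sum matches its output delta y(x) - y(x0)), and the
#' per-position profile aggregates the attributions of every window covering
#' that position (arithmetic mean by default).
#'
#' @inheritParams shap_like
#' @param window,stride Window geometry in residues (defaults 32/16; spans
#'   are exactly [window_spans()]).
#' @param steps Integration steps per window.
#' @param baseline `"pad"` or `"zero"` reference embedding.
#' @param aggregate `"mean"` (default) or `"sum"` across covering windows.
#' @return Object of class `windowed_attribution`: list with `profile`
#'   (tibble: position, residue, score, n_windows), `windows` (tibble:
#'   index, start, end, delta_y, attribution_sum), and the geometry.
#' @export
deeplift_windowed <- function(model, sequence, target_tag, window = 32L,
                              stride = 16L, steps = 32L,
                              baseline = c("pad", "zero"),
                              aggregate = c("mean", "sum")) {
  model <- as_pt_model(model)
  baseline <- match.arg(baseline)
  aggregate <- match.arg(aggregate)
  if (!nzchar(sequence)) abort("empty sequence")
  if (window > model$config$context_length)
    abort("`window` exceeds the model context length")
  L <- nchar(sequence)
  spans <- window_spans(L, window, stride)
  acc <- numeric(L); cover <- integer(L)
  wrows <- vector("list", nrow(spans))
  for (w in seq_len(nrow(spans))) {
    s1 <- spans$start[w] + 1L; e1 <- spans$end[w] + 1L
    sub <- substr(sequence, s1, e1)
    ig <- integrated_gradients(model, sub, target_tag, steps = steps,
                               baseline = baseline)
    pos <- s1:e1
    acc[pos] <- acc[pos] + ig$score
    cover[pos] <- cover[pos] + 1L
    wrows[[w]] <- tibble::tibble(
      index = spans$index[w], start = spans$start[w], end = spans$end[w],
      delta_y = attr(ig, "f_input") - attr(ig, "f_baseline"),
      attribution_sum = sum(ig$score))
  }
  score <- if (aggregate == "mean") acc / pmax(cover, 1L) else acc
  structure(list(
    profile = tibble::tibble(position = seq_len(L), residue = chars(sequence),
                             score = score, n_windows = cover),
    windows = dplyr::bind_rows(wrows),
    window = window, stride = stride, baseline = baseline,
    target = target_tag, aggregate = aggregate
  ), class = "windowed_attribution")
}

#' @export
print.windowed_attribution <- function(x, ...) {
  cat(sprintf("<windowed_attribution> %d positions, %d windows (w=%d, stride=%d, %s baseline)\n",
              nrow(x$profile), nrow(x$windows), x$window, x$stride, x$baseline))
  invisible(x)
}
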