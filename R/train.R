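#' Optimization settings for model training
#'
#' AdamW with decoupled weight decay and a cosine learning-rate schedule
#' with linear warmup. At desk scale (a ~100k-parameter model trained from
#' scratch) a peak rate of 1e-3 converges in a few hundred steps; batch size
#' 64 sits in the range where tag classification is stable.
#'
#' @param batch_size Sequences per optimization step.
#' @param learning_rate Peak learning rate (> 0).
#' @param weight_decay Decoupled weight decay applied to weight matrices.
#' @param warmup_steps Linear warmup length in steps.
#' @param max_steps Total optimization steps.
#' @param seed Integer seed covering batching and initialization.
#' @param eval_every Evaluate (and checkpoint) every this many steps.
#' @param log_every Record a training-log row every this many steps.
#' @return List of class `pt_training`.
#' @export
training_config <- function(batch_size = 64L, learning_rate = 1e-3,
                            weight_decay = 0.01, warmup_steps = 50L,
                            max_steps = 300L, seed = 42L,
                            eval_every = 50L, log_every = 10L) {
  if (batch_size < 1) abort("`batch_size` must be >= 1")
  if (learning_rate <= 0) abort("`learning_rate` must be > 0")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 warmup_steps = as.integer(warmup_steps),
                 max_steps = as.integer(max_steps), seed = as.integer(seed),
                 eval_every = as.integer(eval_every),
                 log_every = as.integer(log_every)),
            class = "pt_training")
}

lr_at <- function(step, tr) {
  if (tr$warmup_steps > 0 && step <= tr$warmup_steps)
    return(tr$learning_rate * step / tr$warmup_steps)
  denom <- max(tr$max_steps - tr$warmup_steps, 1L)
  prog <- (step - tr$warmup_steps) / denom
  tr$learning_rate * 0.5 * (1 + cos(pi * min(prog, 1)))
}

# Build the training string for one dataset item.
training_strings <- function(text, label, tag_map, mode) {
  tag <- unname(tag_map[label])
  if (mode == "tifree") {
    paste0(text, tag)
  } else {
    ifelse(grepl("<", text, fixed = TRUE), text, paste0(text, "<", tag))
  }
}

encode_matrix <- function(texts, vocab, pad_to) {
  t(vapply(texts, encode_text, integer(pad_to), vocab = vocab,
           pad_to = pad_to, USE.NAMES = FALSE))
}

# Cross-entropy over next-token targets; pad targets are masked out of the
# loss. Returns mean nats per unmasked target and the logits gradient.
pt_loss_grad <- function(fw, ids_mat, padid, want_grad = TRUE) {
  B <- nrow(ids_mat); T <- ncol(ids_mat)
  tg <- cbind(ids_mat[, -1, drop = FALSE], padid)    # target for position t is token t+1
  tg_flat <- as.vector(t(tg))
  cur_flat <- as.vector(t(ids_mat))
  pos_flat <- rep(seq_len(T), B)
  valid <- tg_flat != padid & cur_flat != padid & pos_flat < T
  n_valid <- sum(valid)
  if (n_valid == 0) abort("no unmasked targets in batch")
  pm <- softmax_rows(fw$logits)
  idx <- cbind(seq_along(tg_flat), tg_flat)
  loss <- -sum(log(pmax(pm[idx][valid], 1e-12))) / n_valid
  if (!want_grad) return(list(loss = loss, dlogits = NULL))
  dlog <- pm
  dlog[idx] <- dlog[idx] - 1
  dlog[!valid, ] <- 0
  list(loss = loss, dlogits = dlog / n_valid)
}

adamw_step <- function(params, grads, state, step, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    if (is.null(gmat)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat * gmat
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (wd > 0 && is.matrix(params[[nm]])) upd <- upd + wd * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

# Forward a set of full training strings in chunks; returns eval loss and
# tag-aggregation macro F1 (tag read at the last prompt position).
eval_pass <- function(model, enc, lens, labels, padid, chunk = 128L) {
  n <- nrow(enc); V <- vocab_size(model$vocab)
  tids <- tag_ids(model$vocab)
  loss_num <- 0; loss_den <- 0L
  pred <- character(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    ids <- enc[s:e, , drop = FALSE]
    fw <- pt_forward_ids(model, ids, keep_cache = FALSE)
    lg <- pt_loss_grad(fw, ids, padid, want_grad = FALSE)
    B <- nrow(ids); T <- ncol(ids)
    tgt <- cbind(as.vector(t(cbind(ids[, -1, drop = FALSE], padid))))
    nv <- sum(tgt != padid & as.vector(t(ids)) != padid & rep(seq_len(T), B) < T)
    loss_num <- loss_num + lg$loss * nv; loss_den <- loss_den + nv
    rows <- (seq_len(B) - 1L) * T + (lens[s:e] - 1L)   # last prompt position
    tag_logits <- fw$logits[rows, tids, drop = FALSE]
    pred[s:e] <- model$classes[max.col(tag_logits, ties.method = "first")]
  }
  f1s <- vapply(model$classes, function(cl) {
    tp <- sum(pred == cl & labels == cl)
    fp <- sum(pred == cl & labels != cl)
    fn <- sum(pred != cl & labels == cl)
    if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  list(loss = loss_num / loss_den, macro_f1 = mean(f1s))
}

#' Train the causal sequence model on a labelled dataset
#'
#' Minimizes the average next-token negative log-likelihood (nats per
#' unmasked token) over the training strings: in `tifree` mode each item is
#' the fixed-length fragment with its class-tag token appended; in
#' `tiinclusive` mode each item is the full sequence, the `"<"` delimiter,
#' and the tag. Pad positions are masked out of the loss. When `eval_data`
#' is supplied the model is evaluated every `eval_every` steps by
#' tag-aggregation macro F1 and the returned weights are the checkpoint with
#' the best eval macro F1 (ties broken toward the earlier step, since
#' over-trained checkpoints degrade).
#'
#' @param dataset Tibble with `text` and `label` columns (e.g. the `train`
#'   split from [assemble_tifree()]).
#' @param config A [model_config()].
#' @param training A [training_config()].
#' @param eval_data Optional tibble with `text` and `label` used for
#'   checkpoint selection.
#' @param classes Class label order (defaults to sorted unique labels); the
#'   order fixes tag assignment and prediction tie-breaking.
#' @param tags Optional single-character tag tokens, parallel to `classes`.
#' @param mode `"tifree"` or `"tiinclusive"`.
#' @param verbose Print progress lines.
#' @return Object of class `pt_fit`: list with `model` (a `pt_model`), `log`
#'   (tibble: step, lr, train_loss, eval_loss, eval_macro_f1), `best_step`,
#'   `best_metric`.
#' @export
train_model <- function(dataset, config = model_config(),
                        training = training_config(), eval_data = NULL,
                        classes = NULL, tags = NULL,
                        mode = c("tifree", "tiinclusive"), verbose = FALSE) {
  mode <- match.arg(mode)
  if (nrow(dataset) == 0) abort("empty training dataset")
  if (!all(c("text", "label") %in% names(dataset)))
    abort("`dataset` needs `text` and `label` columns")
  if (is.null(classes)) classes <- sort(unique(dataset$label))
  vocab <- aa_vocabulary(classes, tags)
  strings <- training_strings(dataset$text, dataset$label, vocab$tag_map, mode)
  pad_to <- max(nchar(strings))
  if (pad_to > config$context_length)
    abort(sprintf("longest training string (%d) exceeds context_length (%d)",
                  pad_to, config$context_length))
  enc <- encode_matrix(strings, vocab, pad_to)
  padid <- pad_id(vocab)

  model <- init_model(vocab, config, seed = training$seed)
  model$mode <- mode
  model$pad_to <- pad_to

  has_eval <- !is.null(eval_data) && nrow(eval_data) > 0
  if (has_eval) {
    ev_strings <- training_strings(eval_data$text, eval_data$label,
                                   vocab$tag_map, mode)
    ev_enc <- encode_matrix(ev_strings, vocab, pad_to)
    ev_lens <- nchar(ev_strings)
  }

  zeros_like <- lapply(model$params, function(p) p * 0)
  state <- list(m = zeros_like, v = zeros_like)
  n <- nrow(enc)
  logs <- vector("list", 0L)
  best <- list(metric = -Inf, step = NA_integer_, params = model$params)

  withr::with_seed(training$seed, {
    for (step in seq_len(training$max_steps)) {
      idx <- sample.int(n, min(training$batch_size, n))
      ids <- enc[idx, , drop = FALSE]
      fw <- pt_forward_ids(model, ids, keep_cache = TRUE)
      lg <- pt_loss_grad(fw, ids, padid)
      if (!is.finite(lg$loss))
        abort(sprintf("non-finite training loss at step %d", step))
      g <- pt_backward_core(model$params, config, fw, lg$dlogits)
      # embedding gradients from dX
      flat <- as.vector(t(ids))
      gt <- rowsum(g$dX, flat)
      tokg <- model$params$tok * 0
      tokg[as.integer(rownames(gt)), ] <- gt
      gp <- rowsum(g$dX, rep(seq_len(ncol(ids)), nrow(ids)))
      posg <- model$params$pos * 0
      posg[as.integer(rownames(gp)), ] <- gp
      g$dX <- NULL
      g$tok <- tokg; g$pos <- posg
      lr <- lr_at(step, training)
      up <- adamw_step(model$params, g, state, step, lr, training$weight_decay)
      model$params <- up$params; state <- up$state

      do_eval <- has_eval && (step %% training$eval_every == 0 ||
                                step == training$max_steps)
      ev <- NULL
      if (do_eval) {
        ev <- eval_pass(model, ev_enc, ev_lens, eval_data$label, padid)
        if (ev$macro_f1 > best$metric) {
          best <- list(metric = ev$macro_f1, step = step, params = model$params)
        }
      }
      if (step %% training$log_every == 0 || do_eval || step == 1L) {
        logs[[length(logs) + 1L]] <- tibble::tibble(
          step = step, lr = lr, train_loss = lg$loss,
          eval_loss = if (is.null(ev)) NA_real_ else ev$loss,
          eval_macro_f1 = if (is.null(ev)) NA_real_ else ev$macro_f1
        )
        if (verbose && (step %% (training$log_every * 5) == 0 || do_eval)) {
          message(sprintf("step %5d  lr %.2e  loss %.4f%s", step, lr, lg$loss,
                          if (!is.null(ev)) sprintf("  eval F1 %.4f", ev$macro_f1) else ""))
        }
      }
    }
  })

  if (has_eval && is.finite(best$metric)) model$params <- best$params
  structure(list(model = model,
                 log = dplyr::bind_rows(logs),
                 best_step = if (has_eval) best$step else training$max_steps,
                 best_metric = if (has_eval) best$metric else NA_real_,
                 config = config, training = training),
            class = "pt_fit")
}

#' @export
print.pt_fit <- function(x, ...) {
  cat(sprintf("<pt_fit> best step %s (eval macro F1 %s); final train loss %.4f\n",
              x$best_step,
              ifelse(is.na(x$best_metric), "-", sprintf("%.4f", x$best_metric)),
              utils::tail(x$log$train_loss, 1)))
  print(x$model)
  invisible(x)
}
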