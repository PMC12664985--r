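# Batched tag prediction for prompts of identical length.
# Returns list(posterior matrix n x n_classes, predicted, tie).
predict_tag_group <- function(model, texts, chunk = 256L) {
  vocab <- model$vocab
  tids <- tag_ids(vocab)
  n <- length(texts)
  post <- matrix(NA_real_, n, length(model$classes),
                 dimnames = list(NULL, model$classes))
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    ids <- t(vapply(texts[s:e], encode_text, integer(nchar(texts[s])),
                    vocab = vocab, USE.NAMES = FALSE))
    fw <- pt_forward_ids(model, ids, keep_cache = FALSE)
    T <- ncol(ids)
    rows <- seq_len(nrow(ids)) * T                  # last position of each prompt
    pm <- softmax_rows(fw$logits[rows, , drop = FALSE])
    post[s:e, ] <- pm[, tids, drop = FALSE]
  }
  best <- max.col(post, ties.method = "first")
  is_max <- post == post[cbind(seq_len(n), best)]
  list(posterior = post,
       predicted = model$classes[best],
       tie = rowSums(is_max) > 1)
}

build_prompt <- function(model, sequence) {
  if (model$mode == "tiinclusive" && !endsWith(sequence, "<"))
    paste0(sequence, "<") else sequence
}

#' Predict the class tag for a single sequence
#'
#' Prompts the model with the sequence (plus the `"<"` delimiter in
#' tag-suffixed mode) and reads the next-token distribution at the first
#' generated position. The posterior is the softmax mass restricted to the
#' class-tag tokens (mass on other tokens is allowed, so tag probabilities
#' sum to at most 1); the prediction is the argmax over tags, ties broken
#' deterministically toward the first class in the configured order and
#' flagged. With `scan_k` set, up to `scan_k` tokens are generated greedily
#' and the first tag token encountered decides; absence of any tag yields
#' `"unknown"`.
#'
#' @param model A `pt_model` or `pt_fit`.
#' @param sequence Amino-acid string.
#' @param scan_k Optional number of generated tokens to scan for a tag
#'   (e.g. 9); `NULL` (default) reads the single first position.
#' @return One-row tibble: `predicted`, `tie`, `n_tokens_scanned`, and one
#'   `p_<class>` posterior column per class.
#' @export
predict_tag <- function(model, sequence, scan_k = NULL) {
  model <- as_pt_model(model)
  if (!nzchar(sequence)) abort("empty sequence")
  prompt <- build_prompt(model, sequence)
  res <- predict_tag_group(model, prompt)
  predicted <- res$predicted
  n_scanned <- 1L
  if (!is.null(scan_k) && scan_k > 1) {
    out <- scan_generate(model, prompt, scan_k)
    predicted <- out$predicted
    n_scanned <- out$n_scanned
  }
  post <- as.list(res$posterior[1, ])
  names(post) <- paste0("p_", model$classes)
  tibble::tibble(predicted = predicted, tie = res$tie[1],
                 n_tokens_scanned = n_scanned, !!!post)
}

# Greedy generation; first generated tag token decides the class.
scan_generate <- function(model, prompt, k) {
  vocab <- model$vocab
  ids <- encode_text(prompt, vocab)
  tids <- tag_ids(vocab)
  for (j in seq_len(k)) {
    if (length(ids) >= model$config$context_length) break
    fw <- pt_forward_ids(model, matrix(ids, nrow = 1), keep_cache = FALSE)
    logits <- fw$logits[length(ids), ]
    logits[pad_id(vocab)] <- -Inf                    # pad is never emitted
    nxt <- which.max(logits)
    if (nxt %in% tids)
      return(list(predicted = model$classes[match(nxt, tids)], n_scanned = j))
    ids <- c(ids, nxt)
  }
  list(predicted = "unknown", n_scanned = k)
}

#' Classify FASTA records by fragment-vote tag aggregation
#'
#' In `tifree` mode each full-length sequence is cut into non-overlapping
#' `frag_len`-residue windows (a trailing remainder shorter than `frag_len`
#' is classified as its own shorter prompt, so whole proteins are covered at
#' inference even though training discards remainders); every fragment is
#' classified and the per-sequence label is the majority vote over fragment
#' tags, ties yielding `"unknown"`. In `tiinclusive` mode the whole sequence
#' is one prompt. The returned table carries a `coverage` attribute: the
#' fraction of inputs that received a non-`"unknown"` prediction.
#'
#' @param model A `pt_model` or `pt_fit`.
#' @param x Tibble with `id` and `sequence` columns, or a FASTA file path.
#' @param frag_len Inference window length in `tifree` mode (default 100,
#'   matching the training fragment length).
#' @return Tibble: `id`, `predicted`, `n_fragments`, `tie`, and `p_<class>`
#'   columns (fragment-averaged posteriors).
#' @export
classify_fasta <- function(model, x, frag_len = 100L) {
  model <- as_pt_model(model)
  records <- if (is.character(x)) read_fasta(x) else x
  if (!all(c("id", "sequence") %in% names(records)))
    abort("records need `id` and `sequence` columns")
  if (nrow(records) == 0)
    return(tibble::tibble(id = character(), predicted = character(),
                          n_fragments = integer(), tie = logical()))
  classes <- model$classes

  if (model$mode == "tiinclusive") {
    frag_tbl <- tibble::tibble(rec = seq_len(nrow(records)),
                               text = vapply(records$sequence,
                                             function(s) build_prompt(model, s),
                                             character(1), USE.NAMES = FALSE))
  } else {
    frag_tbl <- dplyr::bind_rows(lapply(seq_len(nrow(records)), function(i) {
      s <- records$sequence[i]
      L <- nchar(s)
      n_full <- L %/% frag_len
      frs <- if (n_full > 0) {
        starts <- (seq_len(n_full) - 1L) * frag_len + 1L
        substring(s, starts, starts + frag_len - 1L)
      } else {
        character(0)
      }
      rem_start <- n_full * frag_len + 1L
      if (rem_start <= L) frs <- c(frs, substring(s, rem_start, L))
      tibble::tibble(rec = i, text = frs)
    }))
  }

  # classify fragments grouped by prompt length so batches stay rectangular
  frag_tbl$len <- nchar(frag_tbl$text)
  frag_tbl$predicted <- NA_character_
  post <- matrix(NA_real_, nrow(frag_tbl), length(classes),
                 dimnames = list(NULL, classes))
  for (L in unique(frag_tbl$len)) {
    sel <- which(frag_tbl$len == L)
    res <- predict_tag_group(model, frag_tbl$text[sel])
    frag_tbl$predicted[sel] <- res$predicted
    post[sel, ] <- res$posterior
  }

  groups <- split(seq_len(nrow(frag_tbl)), frag_tbl$rec)
  recs <- as.integer(names(groups))
  pred <- character(length(groups)); tie <- logical(length(groups))
  nfrag <- integer(length(groups))
  pmean <- matrix(NA_real_, length(groups), length(classes),
                  dimnames = list(NULL, paste0("p_", classes)))
  for (k in seq_along(groups)) {
    ii <- groups[[k]]
    votes <- table(factor(frag_tbl$predicted[ii], levels = classes))
    top <- names(votes)[votes == max(votes)]
    tie[k] <- length(top) > 1
    pred[k] <- if (tie[k]) "unknown" else top
    nfrag[k] <- length(ii)
    pmean[k, ] <- colMeans(post[ii, , drop = FALSE])
  }
  ord <- order(recs)
  res <- dplyr::bind_cols(
    tibble::tibble(id = records$id[recs[ord]], predicted = pred[ord],
                   n_fragments = nfrag[ord], tie = tie[ord]),
    tibble::as_tibble(pmean[ord, , drop = FALSE])
  )
  attr(res, "coverage") <- mean(res$predicted != "unknown")
  res
}
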