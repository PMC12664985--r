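#' Position-wise influence profile from layer hidden states
#'
#' For every layer, the influence of position i is the L2 norm of the
#' deviation of its hidden state from the layer's mean hidden state,
#' `||h_i - mu||_2`. Each layer's scores are min-max normalized to [0, 1],
#' then averaged across layers into a single per-position profile, itself
#' min-max normalized (a constant raw profile normalizes to all zeros).
#'
#' @param hidden List of positions x d hidden-state matrices, one per layer
#'   (e.g. `forward_states(model, x)$hidden`); all must share the position
#'   count.
#' @param percentile Height percentile stored as the default peak threshold.
#' @return Object of class `influence_profile`: list with `per_layer` (raw
#'   layers x positions matrix), `avg_influence` (normalized per-position
#'   vector), `threshold`.
#' @export
influence_profile <- function(hidden, percentile = 95) {
  if (length(hidden) == 0) abort("`hidden` must contain at least one layer")
  npos <- unique(vapply(hidden, nrow, integer(1)))
  if (length(npos) != 1) abort("all layers must share the position count")
  raw <- t(vapply(hidden, function(H) {
    sqrt(rowSums(sweep(H, 2, colMeans(H))^2))
  }, numeric(npos)))
  norm <- t(apply(raw, 1, minmax_norm))
  avg <- minmax_norm(colMeans(norm))
  structure(list(per_layer = raw, avg_influence = avg,
                 threshold = pctl(avg, percentile), percentile = percentile),
            class = "influence_profile")
}

#' Class-separation index of residue identities at aligned positions
#'
#' For residue identity a at position i, `I(a, i)` is the Euclidean distance
#' between the mean embedding of tokens carrying a at i and the mean
#' embedding of the complementary tokens at i. The high-importance threshold
#' theta is the given percentile of all defined I values, and the seed set M
#' collects every (sequence, position) whose residue exceeds theta —
#' residues whose identity contributes unusually strongly at their column.
#'
#' @param embeddings List (one element per sequence) of positions x d
#'   matrices — token embeddings or any layer's hidden states. All
#'   sequences must share the position count (aligned fixed-length
#'   fragments).
#' @param sequences Character vector of the sequences, parallel to
#'   `embeddings`.
#' @param percentile Threshold percentile (default 95, linear
#'   interpolation).
#' @return Object of class `class_separation`: list with `I` (residues x
#'   positions matrix, NA where the complement set is empty), `theta`,
#'   `seeds` (tibble: seq_index, position, residue, I), `n_excluded`.
#' @export
class_separation <- function(embeddings, sequences, percentile = 95) {
  if (length(embeddings) != length(sequences))
    abort("`embeddings` and `sequences` must be parallel")
  L <- unique(nchar(sequences))
  if (length(L) != 1) abort("sequences must share a common length")
  if (any(vapply(embeddings, nrow, integer(1)) < L))
    abort("each embedding matrix needs one row per residue")
  res_mat <- do.call(rbind, lapply(sequences, chars))
  alphabet <- sort(unique(as.vector(res_mat)))
  if (length(alphabet) < 2) abort("need >= 2 distinct residues")
  I <- matrix(NA_real_, length(alphabet), L, dimnames = list(alphabet, NULL))
  n_excluded <- 0L
  for (i in seq_len(L)) {
    rows <- t(vapply(embeddings, function(E) E[i, ], numeric(ncol(embeddings[[1]]))))
    here <- res_mat[, i]
    for (a in unique(here)) {
      inA <- here == a
      if (all(inA)) { n_excluded <- n_excluded + 1L; next }
      mu_in <- colMeans(rows[inA, , drop = FALSE])
      mu_out <- colMeans(rows[!inA, , drop = FALSE])
      I[a, i] <- sqrt(sum((mu_in - mu_out)^2))
    }
  }
  vals <- I[!is.na(I)]
  theta <- pctl(vals, percentile)
  seed_idx <- which(matrix(TRUE, length(sequences), L), arr.ind = TRUE)
  sI <- I[cbind(match(res_mat[seed_idx], alphabet), seed_idx[, 2])]
  keep <- !is.na(sI) & sI > theta
  seeds <- tibble::tibble(seq_index = seed_idx[keep, 1],
                          position = seed_idx[keep, 2],
                          residue = res_mat[seed_idx[keep, , drop = FALSE]],
                          I = sI[keep])
  seeds <- dplyr::arrange(seeds, .data$seq_index, .data$position)
  structure(list(I = I, theta = theta, seeds = seeds,
                 n_excluded = n_excluded, percentile = percentile),
            class = "class_separation")
}

motif_tibble <- function(pattern, start, mean_influence, mode) {
  tibble::tibble(pattern = pattern, start = start, length = nchar(pattern),
                 mean_influence = mean_influence, mode = mode)
}

#' Flexible (degenerate) motif discovery from an influence profile
#'
#' Peaks of the averaged influence profile — local maxima at or above the
#' height threshold (the given percentile of the profile) separated by at
#' least `window_size` positions — seed candidate motifs: a `window_size`
#' window centred on each peak, in which positions below the threshold are
#' masked to `"X"`. Windows with at least two above-threshold residues are
#' kept, overlapping or adjacent windows are merged (mean influence
#' combined as the length-weighted mean), and motifs are ranked by mean
#' influence. Because the threshold is a percentile, the output is
#' invariant to monotone rescaling of the profile.
#'
#' @param profile An [influence_profile()] or a numeric per-position vector.
#' @param sequence The sequence the profile belongs to (same length).
#' @param window_size Motif window in residues (default 5); also the
#'   minimum inter-peak distance.
#' @param percentile Height threshold percentile (default 95).
#' @return Tibble: `pattern` (degenerate, `"X"` = unconstrained), `start`
#'   (1-based), `length`, `mean_influence`, `mode = "flexible"`; ranked by
#'   mean influence, descending.
#' @export
flexible_motifs <- function(profile, sequence, window_size = 5L,
                            percentile = 95) {
  avg <- if (inherits(profile, "influence_profile")) profile$avg_influence else profile
  L <- nchar(sequence)
  if (length(avg) != L) abort("profile length must equal sequence length")
  thr <- pctl(avg, percentile)
  peaks <- find_peaks(avg, height = thr, distance = window_size)
  if (length(peaks) == 0) return(motif_tibble(character(), integer(), numeric(), character()))
  half <- (window_size - 1L) %/% 2L
  spans <- lapply(peaks, function(p) {
    s <- p - half
    e <- s + window_size - 1L
    if (e > L) { e <- L; s <- max(1L, e - window_size + 1L) }
    if (s < 1L) { s <- 1L; e <- min(L, s + window_size - 1L) }
    c(s, e)
  })
  cand <- lapply(spans, function(se) {
    idx <- se[1]:se[2]
    above <- avg[idx] >= thr
    if (sum(above) < 2) return(NULL)
    list(start = se[1], end = se[2], mean = mean(avg[idx]))
  })
  cand <- Filter(Negate(is.null), cand)
  if (length(cand) == 0) return(motif_tibble(character(), integer(), numeric(), character()))
  cand <- cand[order(vapply(cand, `[[`, numeric(1), "start"))]
  merged <- list(cand[[1]])
  for (cc in cand[-1]) {
    last <- merged[[length(merged)]]
    if (cc$start <= last$end + 1L) {      # overlap or adjacency: merge
      w1 <- last$end - last$start + 1L
      w2 <- cc$end - cc$start + 1L
      merged[[length(merged)]] <- list(
        start = last$start, end = max(last$end, cc$end),
        mean = (last$mean * w1 + cc$mean * w2) / (w1 + w2))
    } else {
      merged[[length(merged) + 1L]] <- cc
    }
  }
  seq_chars <- chars(sequence)
  out <- dplyr::bind_rows(lapply(merged, function(mo) {
    idx <- mo$start:mo$end
    pat <- ifelse(avg[idx] >= thr, seq_chars[idx], "X")
    motif_tibble(paste(pat, collapse = ""), mo$start, mo$mean, "flexible")
  }))
  dplyr::arrange(out, dplyr::desc(.data$mean_influence))
}

#' Strict motif extraction from a composite attribution score
#'
#' Combines three per-position channels — hidden-state divergence,
#' self-attention diagonal, and integrated gradients — each min-max
#' normalized, into `composite = 0.4 * divergence + 0.3 * attention + 0.3 *
#' ig`. Every window of `min_len` to `max_len` residues is accepted when its
#' mean composite exceeds the profile's percentile threshold AND at least
#' `coverage` of its residues individually exceed that threshold. Accepted
#' windows are returned fully specified (windows containing the ambiguity
#' residue `"X"` are skipped), ranked by mean composite score.
#'
#' @param divergence,attention,ig Numeric per-position channels of equal
#'   length (raw scales allowed; normalized internally).
#' @param sequence Sequence of the same length.
#' @param min_len,max_len Motif length bounds (defaults 3 and 9).
#' @param percentile Composite threshold percentile (default 95).
#' @param coverage Minimum fraction of above-threshold residues per window
#'   (default 0.75).
#' @return Tibble: `pattern`, `start` (1-based), `length`, `mean_influence`
#'   (mean composite), `mode = "strict"`.
#' @export
strict_motifs <- function(divergence, attention, ig, sequence,
                          min_len = 3L, max_len = 9L, percentile = 95,
                          coverage = 0.75) {
  L <- nchar(sequence)
  if (length(divergence) != L || length(attention) != L || length(ig) != L)
    abort("all channels must match the sequence length")
  comp <- 0.4 * minmax_norm(divergence) + 0.3 * minmax_norm(attention) +
    0.3 * minmax_norm(ig)
  thr <- pctl(comp, percentile)
  seq_chars <- chars(sequence)
  rows <- list()
  for (len in seq(min_len, max_len)) {
    if (len > L) break
    for (s in seq_len(L - len + 1L)) {
      idx <- s:(s + len - 1L)
      win <- comp[idx]
      if (mean(win) > thr && mean(win > thr) >= coverage) {
        if (any(seq_chars[idx] == "X")) next
        rows[[length(rows) + 1L]] <-
          motif_tibble(paste(seq_chars[idx], collapse = ""), s, mean(win), "strict")
      }
    }
  }
  if (length(rows) == 0) return(motif_tibble(character(), integer(), numeric(), character()))
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$mean_influence))
}

#' Mean self-attention per position
#'
#' How much each position attends to itself: the attention weight from
#' position i to itself, averaged over all layers and heads, then min-max
#' normalized. Under causal softmax the first position always attends fully
#' to itself (raw weight 1).
#'
#' @param model A `pt_model` or `pt_fit` with at least one attention layer.
#' @param sequence Amino-acid string.
#' @return Numeric vector of normalized self-attention scores with the raw
#'   (unnormalized, in [0, 1]) mean diagonal as attribute `"raw"`.
#' @export
attention_self_diagonal <- function(model, sequence) {
  model <- as_pt_model(model)
  if (model$config$n_layers < 1)
    abort("model has no attention layers")
  fs <- forward_states(model, sequence)
  n <- length(fs$tokens)
  diags <- vapply(fs$attention, function(A) {
    if (n == 1) return(mean(A[1, 1, ]))
    rowMeans(apply(A, 3, diag))
  }, numeric(n))
  raw <- rowMeans(matrix(diags, nrow = n))
  out <- minmax_norm(raw)
  attr(out, "raw") <- raw
  out
}
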