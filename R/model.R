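#' Architecture configuration for the causal sequence model
#'
#' Desk-scale defaults (2 layers, d = 64, 4 heads, context 128) train in
#' minutes on one CPU while preserving the multi-layer, multi-head structure
#' the interpretability tools interrogate; all sizes scale upward.
#'
#' @param n_layers Number of transformer blocks (>= 0; 0 gives a bare
#'   embedding + output-projection model, useful as a linear surrogate).
#' @param d_model Embedding/hidden width.
#' @param n_heads Attention heads; must divide `d_model`.
#' @param context_length Maximum sequence length (positions with learned
#'   positional embeddings).
#' @param mlp_mult Width multiplier of the position-wise MLP.
#' @param final_layernorm Apply layer normalization before the output
#'   projection (disable to make a 0-layer model exactly linear in its
#'   input embeddings).
#' @return List of class `pt_config`.
#' @export
model_config <- function(n_layers = 2L, d_model = 64L, n_heads = 4L,
                         context_length = 128L, mlp_mult = 4L,
                         final_layernorm = TRUE) {
  if (n_layers < 0) abort("`n_layers` must be >= 0")
  if (n_heads >= 1 && d_model %% n_heads != 0)
    abort("`n_heads` must divide `d_model`")
  structure(list(n_layers = as.integer(n_layers), d_model = as.integer(d_model),
                 n_heads = as.integer(n_heads),
                 context_length = as.integer(context_length),
                 mlp_mult = as.integer(mlp_mult),
                 final_layernorm = isTRUE(final_layernorm)),
            class = "pt_config")
}

layer_par_names <- function(i) {
  paste0("l", i, "_",
         c("g1", "b1", "Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
           "g2", "b2", "W1", "c1", "W2", "c2"))
}

#' Initialize model weights
#'
#' Gaussian init (sd 0.02) with the residual output projections scaled by
#' `1/sqrt(2 * n_layers)`, the usual recipe for stable depth scaling.
#'
#' @param vocab An [aa_vocabulary()].
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return Object of class `pt_model`.
#' @export
init_model <- function(vocab, config = model_config(), seed = 1L) {
  V <- vocab_size(vocab); d <- config$d_model; ctx <- config$context_length
  dm <- config$mlp_mult * d
  resid_sd <- if (config$n_layers > 0) 0.02 / sqrt(2 * config$n_layers) else 0.02
  params <- withr::with_seed(seed, {
    p <- list(
      tok = matrix(stats::rnorm(V * d, 0, 0.02), V, d),
      pos = matrix(stats::rnorm(ctx * d, 0, 0.02), ctx, d)
    )
    for (i in seq_len(config$n_layers)) {
      lp <- list(
        rep(1, d), rep(0, d),
        matrix(stats::rnorm(d * d, 0, 0.02), d, d), rep(0, d),
        matrix(stats::rnorm(d * d, 0, 0.02), d, d), rep(0, d),
        matrix(stats::rnorm(d * d, 0, 0.02), d, d), rep(0, d),
        matrix(stats::rnorm(d * d, 0, resid_sd), d, d), rep(0, d),
        rep(1, d), rep(0, d),
        matrix(stats::rnorm(d * dm, 0, 0.02), d, dm), rep(0, dm),
        matrix(stats::rnorm(dm * d, 0, resid_sd), dm, d), rep(0, d)
      )
      names(lp) <- layer_par_names(i)
      p <- c(p, lp)
    }
    p$gf <- rep(1, d); p$bf <- rep(0, d)
    p$Wout <- matrix(stats::rnorm(d * V, 0, 0.02), d, V)
    p$bout <- rep(0, V)
    p
  })
  structure(list(params = params, config = config, vocab = vocab,
                 classes = vocab$classes, tag_map = vocab$tag_map,
                 mode = "tifree", pad_to = NULL),
            class = "pt_model")
}

# ---- layer primitives -------------------------------------------------------

ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x); xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, g, `*`) + matrix(b, nrow(x), length(b), byrow = TRUE),
       xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxh <- sweep(dy, 2, g, `*`)
  dx <- (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) * cache$inv
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

add_bias <- function(x, b) x + matrix(b, nrow(x), length(b), byrow = TRUE)

softmax_rows <- function(s) {
  m <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - m)
  e / rowSums(e)
}

# ---- forward / backward core ------------------------------------------------
# X: (B*T) x d input embeddings (token + positional), rows grouped in blocks
# of T per sequence. `need`: "logits" (training fast path keeps caches),
# "states" additionally records per-layer hidden states and attention.

pt_forward_core <- function(params, cfg, X, B, T, need = "logits",
                            keep_cache = TRUE) {
  nl <- cfg$n_layers; H <- cfg$n_heads
  hidden <- if (need == "states") list(hidden_to_mats(X, B, T)) else NULL
  attn <- if (need == "states") vector("list", max(nl, 0)) else NULL
  caches <- if (keep_cache) vector("list", max(nl, 0)) else NULL
  for (l in seq_len(nl)) {
    g1 <- params[[paste0("l", l, "_g1")]]; b1 <- params[[paste0("l", l, "_b1")]]
    lnc <- ln_fwd(X, g1, b1)
    Q <- add_bias(lnc$y %*% params[[paste0("l", l, "_Wq")]], params[[paste0("l", l, "_bq")]])
    K <- add_bias(lnc$y %*% params[[paste0("l", l, "_Wk")]], params[[paste0("l", l, "_bk")]])
    Vv <- add_bias(lnc$y %*% params[[paste0("l", l, "_Wv")]], params[[paste0("l", l, "_bv")]])
    at <- attn_fwd_cpp(Q, K, Vv, T, H)
    Y <- add_bias(at$O %*% params[[paste0("l", l, "_Wo")]], params[[paste0("l", l, "_bo")]])
    X1 <- X + Y
    ln2c <- ln_fwd(X1, params[[paste0("l", l, "_g2")]], params[[paste0("l", l, "_b2")]])
    A1 <- add_bias(ln2c$y %*% params[[paste0("l", l, "_W1")]], params[[paste0("l", l, "_c1")]])
    R1 <- pmax(A1, 0)
    X2 <- X1 + add_bias(R1 %*% params[[paste0("l", l, "_W2")]], params[[paste0("l", l, "_c2")]])
    if (keep_cache) {
      caches[[l]] <- list(lnc = lnc, Q = Q, K = K, Vv = Vv, P = at$P, O = at$O,
                          X1 = X1, ln2c = ln2c, A1 = A1, R1 = R1)
    }
    if (need == "states") {
      hidden[[l + 1L]] <- hidden_to_mats(X2, B, T)
      attn[[l]] <- at$P
    }
    X <- X2
  }
  if (cfg$final_layernorm) {
    lnf <- ln_fwd(X, params$gf, params$bf)
    Xf <- lnf$y
  } else {
    lnf <- NULL
    Xf <- X
  }
  logits <- add_bias(Xf %*% params$Wout, params$bout)
  list(logits = logits, caches = caches, lnf = lnf, X_final = X,
       hidden = hidden, attn = attn, B = B, T = T)
}

hidden_to_mats <- function(X, B, T) {
  lapply(seq_len(B), function(b) X[((b - 1L) * T + 1L):(b * T), , drop = FALSE])
}

# Backward pass. dlogits: (B*T) x V. Returns named gradient list (parameter
# names as in `params`) plus `dX`, the gradient w.r.t. the input embeddings.
pt_backward_core <- function(params, cfg, fw, dlogits) {
  nl <- cfg$n_layers; H <- cfg$n_heads; T <- fw$T
  g <- list()
  Xf <- if (cfg$final_layernorm) fw$lnf$y else fw$X_final
  g$Wout <- crossprod(Xf, dlogits)
  g$bout <- colSums(dlogits)
  dXf <- tcrossprod(dlogits, params$Wout)
  if (cfg$final_layernorm) {
    bb <- ln_bwd(dXf, fw$lnf, params$gf)
    g$gf <- bb$dg; g$bf <- bb$db
    dX <- bb$dx
  } else {
    g$gf <- rep(0, cfg$d_model); g$bf <- rep(0, cfg$d_model)
    dX <- dXf
  }
  for (l in rev(seq_len(nl))) {
    ca <- fw$caches[[l]]
    nm <- function(s) paste0("l", l, "_", s)
    dR1 <- tcrossprod(dX, params[[nm("W2")]])
    g[[nm("W2")]] <- crossprod(ca$R1, dX)
    g[[nm("c2")]] <- colSums(dX)
    dA1 <- dR1 * (ca$A1 > 0)
    g[[nm("W1")]] <- crossprod(ca$ln2c$y, dA1)
    g[[nm("c1")]] <- colSums(dA1)
    dln2y <- tcrossprod(dA1, params[[nm("W1")]])
    b2 <- ln_bwd(dln2y, ca$ln2c, params[[nm("g2")]])
    g[[nm("g2")]] <- b2$dg; g[[nm("b2")]] <- b2$db
    dX1 <- dX + b2$dx
    dO <- tcrossprod(dX1, params[[nm("Wo")]])
    g[[nm("Wo")]] <- crossprod(ca$O, dX1)
    g[[nm("bo")]] <- colSums(dX1)
    ab <- attn_bwd_cpp(dO, ca$Q, ca$K, ca$Vv, ca$P, T, H)
    g[[nm("Wq")]] <- crossprod(ca$lnc$y, ab$dQ); g[[nm("bq")]] <- colSums(ab$dQ)
    g[[nm("Wk")]] <- crossprod(ca$lnc$y, ab$dK); g[[nm("bk")]] <- colSums(ab$dK)
    g[[nm("Wv")]] <- crossprod(ca$lnc$y, ab$dV); g[[nm("bv")]] <- colSums(ab$dV)
    dlny <- tcrossprod(ab$dQ, params[[nm("Wq")]]) +
      tcrossprod(ab$dK, params[[nm("Wk")]]) +
      tcrossprod(ab$dV, params[[nm("Wv")]])
    b1 <- ln_bwd(dlny, ca$lnc, params[[nm("g1")]])
    g[[nm("g1")]] <- b1$dg; g[[nm("b1")]] <- b1$db
    dX <- dX1 + b1$dx
  }
  g$dX <- dX
  g
}

# Embed a batch of id rows (B x T matrix) into the (B*T) x d input matrix.
pt_embed <- function(model, ids_mat) {
  B <- nrow(ids_mat); T <- ncol(ids_mat)
  if (T > model$config$context_length)
    abort(sprintf("sequence length %d exceeds context_length %d",
                  T, model$config$context_length))
  flat <- as.vector(t(ids_mat))
  model$params$tok[flat, , drop = FALSE] +
    model$params$pos[rep(seq_len(T), B), , drop = FALSE]
}

# Forward a batch of ids; returns logits array and optionally states.
pt_forward_ids <- function(model, ids_mat, need = "logits", keep_cache = FALSE) {
  V <- vocab_size(model$vocab)
  if (any(ids_mat < 1 | ids_mat > V)) abort("token id out of range")
  X <- pt_embed(model, ids_mat)
  pt_forward_core(model$params, model$config, X, nrow(ids_mat), ncol(ids_mat),
                  need = need, keep_cache = keep_cache)
}

#' Run the model and expose logits, embeddings, and per-layer hidden states
#'
#' Layer 0 of `hidden` is the input embedding after positional mixing; layer
#' `l` is the output of block `l`, so an `n_layers`-block model yields
#' `n_layers + 1` hidden matrices. `attention` holds, per block, the causal
#' softmax attention weights as a `T x T x n_heads` array.
#'
#' @param model A `pt_model` (or `pt_fit`).
#' @param x A string (encoded with the model vocabulary, unpadded) or an
#'   integer id vector.
#' @return List with `logits` (T x V, pre-softmax rows), `embeddings`
#'   (T x d token embeddings), `hidden` (list of T x d matrices), and
#'   `attention` (list of arrays), plus `tokens` (the id vector).
#' @export
forward_states <- function(model, x) {
  model <- as_pt_model(model)
  ids <- if (is.character(x)) encode_text(x, model$vocab) else as.integer(x)
  if (length(ids) == 0) abort("zero-length input")
  fw <- pt_forward_ids(model, matrix(ids, nrow = 1), need = "states")
  list(logits = fw$logits,
       embeddings = model$params$tok[ids, , drop = FALSE],
       hidden = lapply(fw$hidden, `[[`, 1),
       attention = fw$attn,
       tokens = ids)
}

as_pt_model <- function(x) {
  if (inherits(x, "pt_fit")) return(x$model)
  if (!inherits(x, "pt_model")) abort("expected a `pt_model` or `pt_fit`")
  x
}

#' @export
print.pt_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<pt_model> %d layer(s), d_model=%d, heads=%d, context=%d, vocab=%d (%s mode, %s params)\n",
    cfg$n_layers, cfg$d_model, cfg$n_heads, cfg$context_length,
    vocab_size(x$vocab), x$mode, format(n_par, big.mark = ",")))
  invisible(x)
}
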