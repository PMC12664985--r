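# Shared fixtures, built in code. The trained toy model is cached for the
# whole test run: a small 2-layer model fitted on a perfectly separable
# two-class corpus (disjoint residue alphabets per class).

.fixture_env <- new.env(parent = emptyenv())

toy_profiles <- function() {
  list(
    a = class_profile("algal",
                      residue_freqs = c(stats::setNames(rep(1 / 3, 3), c("Q", "A", "R")),
                                        stats::setNames(rep(0, 17),
                                                        setdiff(AA_ALPHABET20, c("Q", "A", "R"))),
                                        X = 0)),
    b = class_profile("bacterial",
                      residue_freqs = c(stats::setNames(rep(1 / 3, 3), c("G", "S", "L")),
                                        stats::setNames(rep(0, 17),
                                                        setdiff(AA_ALPHABET20, c("G", "S", "L"))),
                                        X = 0))
  )
}

# 20-residue fragments from disjoint alphabets; trains to separation in
# a couple hundred steps at desk scale.
toy_dataset <- function(n_per_class = 80, frag_len = 20, seed = 11) {
  prof <- toy_profiles()
  pools <- lapply(prof, function(p) {
    rec <- generate_proteome(p, ceiling(n_per_class * frag_len / 250) + 5,
                             seed = seed + match(p$class_label, c("algal", "bacterial")))
    fragment_unisequence(build_unisequence(rec), frag_len)[seq_len(n_per_class)]
  })
  names(pools) <- vapply(prof, `[[`, character(1), "class_label")
  assemble_tifree(pools, seed = seed)
}

toy_fit <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  ds <- toy_dataset()
  tr <- ds[ds$split == "train", ]
  ev <- ds[ds$split == "eval", ]
  fit <- train_model(
    tr,
    config = model_config(n_layers = 2, d_model = 32, n_heads = 4,
                          context_length = 32),
    training = training_config(batch_size = 32, max_steps = 400,
                               learning_rate = 2e-3, warmup_steps = 20,
                               eval_every = 100, seed = 5),
    eval_data = ev
  )
  .fixture_env$fit <- fit
  fit
}

# 0-layer model without final layer norm: logits are exactly linear in the
# input embeddings, giving closed-form oracles for the attribution methods.
linear_model <- function(seed = 2, d = 8) {
  vocab <- aa_vocabulary(c("a", "b"))
  m <- init_model(vocab,
                  model_config(n_layers = 0, d_model = d, n_heads = 1,
                               context_length = 16, final_layernorm = FALSE),
                  seed = seed)
  m
}

# model whose logits are constant (zero output projection)
constant_model <- function(seed = 4) {
  m <- linear_model(seed)
  m$params$Wout <- m$params$Wout * 0
  m$params$bout <- m$params$bout * 0
  m
}

pt_ns <- asNamespace("proteotag")
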