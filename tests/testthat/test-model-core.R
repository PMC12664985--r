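test_that("encoding round-trips, pads, and maps ambiguity codes to X", {
  vocab <- aa_vocabulary(c("a", "b"))
  ids <- encode_text("ACD", vocab, pad_to = 5)
  expect_length(ids, 5)
  expect_equal(decode_ids(ids, vocab), "ACD")
  expect_equal(sum(ids == match("_", vocab$tokens)), 2)

  ids2 <- encode_text("AB?D", vocab)
  xid <- match("X", vocab$tokens)
  expect_equal(ids2[c(2, 3)], c(xid, xid))

  expect_error(encode_text("ACDEFG", vocab, pad_to = 5), "exceeds")
  expect_error(decode_ids(c(1L, 999L), vocab), "out of range")
  expect_error(aa_vocabulary(c("a", "a")), "distinct")
})

test_that("forward exposes correctly shaped states with normalized logits", {
  m <- toy_fit()$model
  fs <- forward_states(m, "QARQARQA")
  n_layers <- m$config$n_layers
  expect_length(fs$hidden, n_layers + 1)
  expect_true(all(vapply(fs$hidden, nrow, integer(1)) == 8))
  expect_true(all(vapply(fs$hidden, ncol, integer(1)) == m$config$d_model))
  expect_equal(dim(fs$logits), c(8, length(m$vocab$tokens)))
  expect_equal(dim(fs$embeddings), c(8, m$config$d_model))
  expect_length(fs$attention, n_layers)
  pm <- exp(fs$logits - apply(fs$logits, 1, max))
  pm <- pm / rowSums(pm)
  expect_equal(rowSums(pm), rep(1, 8), tolerance = 1e-6)
  # attention rows are probability distributions over visible positions
  A <- fs$attention[[1]]
  expect_equal(apply(A, 3, rowSums), matrix(1, 8, m$config$n_heads))
})

test_that("logits are causal: suffix perturbation leaves prefixes unchanged", {
  m <- toy_fit()$model
  vocab <- m$vocab
  base_ids <- encode_text("QARQGSLS", vocab)
  base <- forward_states(m, base_ids)$logits
  for (t in 2:8) {
    mut <- base_ids
    mut[t] <- (mut[t] %% 20) + 1L
    pert <- forward_states(m, mut)$logits
    expect_lt(max(abs(pert[1:(t - 1), ] - base[1:(t - 1), ])), 1e-9)
  }
})

test_that("a zero-logit model scores ln(V) nats per token", {
  m <- constant_model()
  vocab <- m$vocab
  ids <- matrix(encode_text("ACDEFGHIKL", vocab), nrow = 1)
  fw <- pt_ns$pt_forward_ids(m, ids)
  lg <- pt_ns$pt_loss_grad(fw, ids, pt_ns$pad_id(vocab), want_grad = FALSE)
  expect_equal(lg$loss, log(length(vocab$tokens)), tolerance = 1e-10)
})

test_that("training memorizes a tiny dataset and is seed-deterministic", {
  ds <- tibble::tibble(
    text = c("QQQAAARRR", "AAARRRQQQ", "GGGSSSLLL", "SSSLLLGGG"),
    label = rep(c("algal", "bacterial"), each = 2)
  )
  cfg <- model_config(n_layers = 1, d_model = 32, n_heads = 2, context_length = 16)
  tr <- training_config(batch_size = 4, max_steps = 400, warmup_steps = 10,
                        learning_rate = 3e-3, seed = 13, log_every = 50)
  fit <- train_model(ds, config = cfg, training = tr)
  expect_lt(utils::tail(fit$log$train_loss, 1), 0.01)   # memorization, nats/token
  expect_lt(utils::tail(fit$log$train_loss, 1), fit$log$train_loss[1])

  fit2 <- train_model(ds, config = cfg, training = tr)
  expect_identical(fit$log, fit2$log)
  expect_equal(fit$model$params, fit2$model$params)

  expect_error(train_model(ds[0, ], config = cfg, training = tr), "empty")
})

test_that("checkpoints round-trip through JSON", {
  fit <- toy_fit()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit, path)
  m2 <- load_model(path)
  s <- "QARQARQARQARQARQARQA"
  expect_equal(predict_tag(m2, s), predict_tag(fit, s))
  expect_equal(m2$config, fit$model$config)
})
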