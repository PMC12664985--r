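# On the 0-layer linear surrogate (no final layer norm) the tag logit read
# at the last position T is F(x) = (e_T + p_T) . w_tag + b_tag — linear in
# the token embeddings and depending only on position T, so every
# attribution method has a closed form: zero off the final position and
# e_T . w_tag (for a zero baseline) at it.

test_that("gradient-times-embedding matches the analytic linear-head contribution", {
  m <- linear_model()
  s <- "ACDE"
  ids <- encode_text(s, m$vocab)
  tag_col <- pt_ns$tag_ids(m$vocab)[1]
  w <- m$params$Wout[, tag_col]
  phi <- shap_like(m, s, "a")
  expect_equal(phi$score, c(0, 0, 0, sum(m$params$tok[ids[4], ] * w)),
               tolerance = 1e-10)
  expect_equal(phi$residue, c("A", "C", "D", "E"))

  # token with a zero embedding row attributes exactly zero
  m0 <- m
  m0$params$tok[match("E", m0$vocab$tokens), ] <- 0
  phi0 <- shap_like(m0, s, "a")
  expect_equal(phi0$score[4], 0)
  expect_error(shap_like(m, "", "a"), "empty")
})

test_that("gradient-times-embedding equals exact Shapley values on the linear game", {
  m <- linear_model()
  s <- "ACDE"
  ids <- encode_text(s, m$vocab)
  tag_col <- pt_ns$tag_ids(m$vocab)[1]
  w <- m$params$Wout[, tag_col]
  # coalition value: tag logit with absent features' embeddings zeroed
  vfun <- function(subset) {
    E <- m$params$tok[ids, , drop = FALSE]
    E[setdiff(1:4, subset), ] <- 0
    X <- E + m$params$pos[1:4, ]
    fw <- pt_ns$pt_forward_core(m$params, m$config, X, 1L, 4L, keep_cache = FALSE)
    fw$logits[4, tag_col]
  }
  phi_exact <- exhaustive_shapley(vfun, 4)
  phi_grad <- shap_like(m, s, "a")$score
  expect_equal(phi_grad, phi_exact, tolerance = 1e-9)
})

test_that("integrated gradients is exact for linear heads and null at baseline", {
  m <- linear_model()
  s <- "ACDE"
  ids <- encode_text(s, m$vocab)
  tag_col <- pt_ns$tag_ids(m$vocab)[1]
  w <- m$params$Wout[, tag_col]
  expected <- c(0, 0, 0, sum(m$params$tok[ids[4], ] * w))
  for (steps in c(1, 5, 50)) {
    ig <- integrated_gradients(m, s, "a", steps = steps, baseline = "zero")
    expect_equal(ig$score, expected, tolerance = 1e-9)
    # completeness is exact for a linear target
    expect_equal(sum(ig$score), attr(ig, "f_input") - attr(ig, "f_baseline"),
                 tolerance = 1e-9)
  }
  # input identical to the baseline: zero attribution everywhere
  mpad <- linear_model()
  padtok <- mpad$vocab$pad
  ig0 <- integrated_gradients(mpad, "____", "a", steps = 5, baseline = "pad")
  expect_equal(ig0$score, rep(0, 4), tolerance = 1e-12)
})

test_that("integrated gradients satisfies completeness on the trained model", {
  fit <- toy_fit()
  s <- "QARQARQARQARQARQARQA"
  ig <- integrated_gradients(fit, s, "algal", steps = 50)
  delta <- attr(ig, "f_input") - attr(ig, "f_baseline")
  expect_equal(sum(ig$score), delta, tolerance = 0.01)

  # quadrature error shrinks as steps grow
  errs <- vapply(c(5, 50, 500), function(k) {
    igk <- integrated_gradients(fit, s, "algal", steps = k)
    abs(sum(igk$score) - (attr(igk, "f_input") - attr(igk, "f_baseline")))
  }, numeric(1))
  expect_true(errs[2] <= errs[1] + 1e-12)
  expect_true(errs[3] <= errs[2] + 1e-12)
})

test_that("all attribution methods vanish for a constant model", {
  m <- constant_model()
  s <- "ACDEFGHI"
  expect_equal(shap_like(m, s, "a")$score, rep(0, 8))
  expect_equal(integrated_gradients(m, s, "a", steps = 5)$score, rep(0, 8))
  dl <- deeplift_windowed(m, s, "a", window = 4, stride = 2, steps = 4)
  expect_equal(dl$profile$score, rep(0, 8))
})

test_that("unknown tags are rejected", {
  expect_error(shap_like(linear_model(), "ACD", "nosuch"), "unknown target")
})
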