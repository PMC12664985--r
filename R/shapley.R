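#' Exact Shapley values by exhaustive subset enumeration
#'
#' Computes, for each feature i, the weighted average of marginal
#' contributions `v(S + i) - v(S)` over all subsets S of the remaining
#' features, with the classical weight `|S|! (n - |S| - 1)! / n!`. This is
#' the exact game-theoretic quantity that gradient-based explainers
#' approximate; it enumerates all `2^n` coalitions and is therefore a test
#' oracle for small n, never a production path.
#'
#' @param value_function Function taking an integer vector of feature
#'   indices (possibly empty) and returning a scalar coalition value.
#' @param n_features Number of features (<= 12; larger inputs are refused).
#' @return Numeric vector of Shapley values, one per feature. Satisfies
#'   efficiency: `sum(phi) == v(1:n) - v(integer(0))`.
#' @examples
#' # additive game: Shapley value of i is its own contribution
#' exhaustive_shapley(function(s) sum(c(1, 2, 3)[s]), 3)
#' @export
exhaustive_shapley <- function(value_function, n_features) {
  if (n_features > 12) abort("refusing n_features > 12 (2^n enumeration)")
  if (n_features < 1) abort("`n_features` must be >= 1")
  n <- as.integer(n_features)
  masks <- 0:(2^n - 1)
  members <- lapply(masks, function(m) which(bitwAnd(m, 2^(0:(n - 1))) > 0))
  vals <- vapply(members, function(s) value_function(s), numeric(1))
  sizes <- lengths(members)
  fact <- factorial(0:n)
  phi <- numeric(n)
  for (i in seq_len(n)) {
    bit <- 2^(i - 1)
    without <- which(bitwAnd(masks, bit) == 0)
    for (m in without) {
      s <- sizes[m]
      w <- fact[s + 1] * fact[n - s] / fact[n + 1]
      phi[i] <- phi[i] + w * (vals[m + bit] - vals[m])
    }
  }
  phi
}
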