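#' @importFrom rlang abort warn
NULL

#' Min-max normalize a numeric vector to [0, 1]
#'
#' Constant input is a guarded degenerate case and maps to all zeros rather
#' than NaN, so downstream percentile thresholds stay well defined.
#'
#' @param x Numeric vector (finite values).
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_norm <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) abort("minmax_norm() requires finite values")
  if (rng[2] == rng[1]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

# Percentile with the linear-interpolation-between-closest-ranks convention
# (stats::quantile type 7), fixed package-wide for reproducibility.
pctl <- function(x, p) unname(stats::quantile(x, p / 100, type = 7, names = FALSE))

#' Locate local maxima with height and minimum-distance constraints
#'
#' Peaks are strict local maxima (plateaus contribute their midpoint). Peaks
#' below `height` are dropped; remaining peaks are pruned greedily from the
#' highest down, removing any peak closer than `distance` positions to an
#' already-kept higher peak.
#'
#' @param x Numeric signal.
#' @param height Minimum peak height (kept if `x >= height`). `-Inf` keeps all.
#' @param distance Minimum separation in positions between kept peaks.
#' @return Integer vector of peak positions (1-based), in increasing order.
#' @export
find_peaks <- function(x, height = -Inf, distance = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  peaks <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        peaks <- c(peaks, as.integer(floor((i + j) / 2)))
        i <- j + 1L
      } else {
        i <- j + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  peaks <- peaks[x[peaks] >= height]
  if (length(peaks) > 1 && distance > 1) {
    ord <- order(x[peaks], -peaks, decreasing = TRUE)
    keep <- rep(TRUE, length(peaks))
    for (k in ord) {
      if (!keep[k]) next
      too_close <- abs(peaks - peaks[k]) < distance & seq_along(peaks) != k
      keep[too_close] <- FALSE
    }
    peaks <- peaks[keep]
  }
  sort(peaks)
}

# split a string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# assert a scalar probability-like value
check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    abort(sprintf("`%s` must be a single value in [0, 1]", name))
  invisible(x)
}
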