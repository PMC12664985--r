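#' Cluster attribution patterns with elbow-selected k-means
#'
#' Rows (one attribution vector per sequence, padded/truncated to a common
#' length beforehand) are z-score standardized per feature, then k-means is
#' run for k = 1..min(10, n). Moving from k-1 to k, the percentage decrease
#' in within-cluster sum of squares (inertia) is
#' `(inertia[k-1] - inertia[k]) / inertia[k-1] * 100`; the selected k is the
#' first whose decrease falls below 20% (diminishing returns), with all
#' remaining ks kept in the curve for inspection. A zero-inertia fit stops
#' the search at that k.
#'
#' @param mat Numeric matrix, sequences x positions.
#' @param max_k Upper bound on k (default 10).
#' @param elbow_pct Diminishing-returns threshold in percent (default 20).
#' @param nstart Random restarts per k (default 10).
#' @param seed Integer seed for the k-means restarts.
#' @return Object of class `attr_clustering`: list with `k_selected`,
#'   `assignments` (integer per row), `inertia_curve` (tibble: k, inertia,
#'   pct_decrease).
#' @export
cluster_attributions <- function(mat, max_k = 10L, elbow_pct = 20,
                                 nstart = 10L, seed = 1L) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 1) abort("need at least one row")
  sds <- apply(mat, 2, stats::sd)
  sds[is.na(sds)] <- 0                       # single-row input
  mu <- colMeans(mat)
  z <- sweep(mat, 2, mu)
  keep <- sds > 0
  z[, keep] <- sweep(z[, keep, drop = FALSE], 2, sds[keep], `/`)
  z[, !keep] <- 0

  kmax <- min(max_k, n)
  n_distinct <- nrow(unique(z))
  inertia <- numeric(kmax)
  fits <- vector("list", kmax)
  withr::with_seed(seed, {
    for (k in seq_len(kmax)) {
      if (k == 1) {
        inertia[k] <- sum(sweep(z, 2, colMeans(z))^2)
        fits[[k]] <- rep(1L, n)
      } else if (k >= n_distinct || k >= nrow(z)) {
        # a perfect (zero-inertia) partition exists; kmeans itself rejects
        # center counts at the row count, so assign distinct rows directly
        inertia[k] <- 0
        fits[[k]] <- as.integer(factor(apply(z, 1, paste, collapse = ",")))
      } else {
        km <- stats::kmeans(z, centers = k, nstart = nstart, iter.max = 50)
        inertia[k] <- km$tot.withinss
        fits[[k]] <- km$cluster
      }
    }
  })
  pct <- c(NA_real_, vapply(2:max(kmax, 2), function(k) {
    if (k > kmax) return(NA_real_)
    if (inertia[k - 1] <= 0) return(NA_real_)
    (inertia[k - 1] - inertia[k]) / inertia[k - 1] * 100
  }, numeric(1)))[seq_len(kmax)]

  k_selected <- kmax
  for (k in seq_len(kmax)) {
    if (k == 1) {
      if (inertia[1] <= 1e-12) { k_selected <- 1L; break }
      next
    }
    if (is.na(pct[k])) { k_selected <- k - 1L; break }     # inertia already zero
    if (pct[k] < elbow_pct) { k_selected <- k; break }
  }
  structure(list(
    k_selected = as.integer(k_selected),
    assignments = fits[[k_selected]],
    inertia_curve = tibble::tibble(k = seq_len(kmax), inertia = inertia,
                                   pct_decrease = pct)
  ), class = "attr_clustering")
}
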