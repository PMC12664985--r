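#' Project one layer's hidden states onto its first two singular axes
#'
#' Uncentered singular value decomposition of the positions x d hidden-state
#' matrix, H = U Sigma V', followed by projection onto the first two right
#' singular vectors: Z = H V[, 1:2]. No mean subtraction is applied by
#' default, matching the decomposition as used on raw hidden states; the
#' `center` option gives the conventional PCA variant. Each right singular
#' vector is sign-fixed so its largest-magnitude entry is positive, making
#' the output deterministic; singular-value ties are resolved in
#' decomposition order and flagged.
#'
#' @param H Numeric matrix, positions x d with d >= 2.
#' @param residues Optional character vector of per-position residues.
#' @param layer Optional layer index carried through to the output.
#' @param center Subtract column means first (default FALSE).
#' @return Object of class `layer_projection`: list with `coords`
#'   (positions x 2), `singular_values` (descending), `rotation` (d x 2),
#'   `residues`, `layer`, `tied` (logical: leading singular values tied).
#' @export
layer_projection <- function(H, residues = NULL, layer = NA_integer_,
                             center = FALSE) {
  H <- as.matrix(H)
  if (ncol(H) < 2) abort("`H` needs at least 2 columns")
  if (nrow(H) < 1) abort("`H` needs at least 1 row")
  if (center) H <- sweep(H, 2, colMeans(H))
  s <- svd(H)
  V2 <- s$v[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i <- which.max(abs(V2[, j]))
    if (V2[i, j] < 0) V2[, j] <- -V2[, j]
  }
  k <- min(3, length(s$d))
  tied <- length(unique(signif(s$d[1:k], 12))) < k
  structure(list(coords = H %*% V2, singular_values = s$d,
                 rotation = V2, residues = residues, layer = layer,
                 tied = tied, centered = center),
            class = "layer_projection")
}

#' Layer-wise SVD projections across the full network depth
#'
#' Runs the model, projects the hidden states of every layer (including
#' layer 0, the input embedding after positional mixing) onto their first
#' two singular axes, and reports a per-layer separation statistic —
#' the mean pairwise distance between residue-identity centroids divided by
#' the mean within-identity spread — quantifying how residue features pull
#' apart with network depth.
#'
#' @param model A `pt_model` or `pt_fit`.
#' @param sequence Amino-acid string.
#' @param center Passed to [layer_projection()].
#' @return Object of class `helix_projection`: list with `projections`
#'   (list of `layer_projection`, layers 0..n_layers) and `separation`
#'   (tibble: layer, separation).
#' @export
project_all_layers <- function(model, sequence, center = FALSE) {
  model <- as_pt_model(model)
  fs <- forward_states(model, sequence)
  residues <- model$vocab$tokens[fs$tokens]
  projections <- lapply(seq_along(fs$hidden), function(i) {
    layer_projection(fs$hidden[[i]], residues = residues,
                     layer = i - 1L, center = center)
  })
  sep <- vapply(projections, function(p) separation_statistic(p$coords, residues),
                numeric(1))
  structure(list(projections = projections,
                 separation = tibble::tibble(layer = seq_along(projections) - 1L,
                                             separation = sep)),
            class = "helix_projection")
}

# mean inter-centroid distance over mean intra-class spread (residue classes)
separation_statistic <- function(Z, classes) {
  groups <- split(seq_along(classes), classes)
  cents <- t(vapply(groups, function(ii) colMeans(Z[ii, , drop = FALSE]),
                    numeric(ncol(Z))))
  if (nrow(cents) < 2) return(NA_real_)
  inter <- mean(stats::dist(cents))
  spreads <- vapply(groups, function(ii) {
    if (length(ii) < 2) return(NA_real_)
    mean(sqrt(rowSums(sweep(Z[ii, , drop = FALSE], 2,
                            colMeans(Z[ii, , drop = FALSE]))^2)))
  }, numeric(1))
  intra <- mean(spreads, na.rm = TRUE)
  if (!is.finite(intra)) return(NA_real_)
  inter / (intra + 1e-12)
}

#' @export
print.helix_projection <- function(x, ...) {
  cat(sprintf("<helix_projection> %d layers (0..%d), %d positions\n",
              length(x$projections), length(x$projections) - 1L,
              nrow(x$projections[[1]]$coords)))
  print(x$separation)
  invisible(x)
}
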