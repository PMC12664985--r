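#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter residue codes, in the conventional
#' alphabetical order used throughout the package. The ambiguity code `"X"`
#' is handled separately wherever it matters.
#'
#' @export
AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Define a class-specific sequence composition profile
#'
#' A profile describes one class of a synthetic two-class proteome: its
#' residue usage, optional planted motifs, and the sequence length range.
#' Profiles drive [generate_proteome()] and together (one per class) define a
#' benchmark corpus with a controlled compositional contrast between classes,
#' emulating the kind of amino-acid usage bias that separates algal from
#' bacterial proteins.
#'
#' @param class_label Single string naming the class (e.g. `"algal"`).
#' @param residue_freqs Named numeric vector of sampling probabilities over
#'   the 20 canonical residues plus `"X"`. Must sum to 1 (tolerance `1e-9`).
#'   If `NULL`, uniform over the 20 canonical residues with `x_prob` mass on
#'   `"X"`.
#' @param enrich Optional named numeric vector, e.g. `c(Q = .12, A = .12)`:
#'   these residues get the stated probabilities and the remaining mass is
#'   spread proportionally over the other residues. Ignored when
#'   `residue_freqs` is given.
#' @param motifs List of planted motifs, each a `list(pattern=, prob=)` pair:
#'   `pattern` a string over the alphabet, `prob` the per-sequence insertion
#'   probability in `[0, 1]`.
#' @param length_range Integer pair `c(min_len, max_len)` of sequence lengths
#'   in residues; lengths are drawn uniformly from this range.
#' @param x_prob Probability mass on the ambiguity code `"X"` when
#'   `residue_freqs` is constructed internally. Default 0.001 so ambiguity
#'   handling is exercised without dominating composition.
#' @return An object of class `class_profile`.
#' @seealso [default_profiles()], [generate_proteome()]
#' @examples
#' p <- class_profile("algal", enrich = c(Q = 0.12, A = 0.12, R = 0.12))
#' sum(p$residue_freqs)
#' @export
class_profile <- function(class_label, residue_freqs = NULL, enrich = NULL,
                          motifs = list(), length_range = c(150L, 450L),
                          x_prob = 0.001) {
  if (!is.character(class_label) || length(class_label) != 1 || !nzchar(class_label))
    abort("`class_label` must be a non-empty string")
  alphabet <- c(AA_ALPHABET20, "X")
  if (is.null(residue_freqs)) {
    base <- stats::setNames(rep((1 - x_prob) / 20, 20), AA_ALPHABET20)
    residue_freqs <- c(base, X = x_prob)
    if (!is.null(enrich)) {
      bad <- setdiff(names(enrich), alphabet)
      if (length(bad)) abort(paste0("unknown residues in `enrich`: ", toString(bad)))
      rest <- setdiff(names(residue_freqs), names(enrich))
      spare <- 1 - sum(enrich)
      if (spare < 0) abort("`enrich` probabilities exceed 1")
      residue_freqs[names(enrich)] <- enrich
      residue_freqs[rest] <- residue_freqs[rest] / sum(residue_freqs[rest]) * spare
    }
  }
  residue_freqs <- residue_freqs[alphabet[alphabet %in% names(residue_freqs)]]
  if (length(setdiff(names(residue_freqs), alphabet)))
    abort("`residue_freqs` names must be the 20 canonical residues plus 'X'")
  if (abs(sum(residue_freqs) - 1) > 1e-9)
    abort("`residue_freqs` must sum to 1 (tolerance 1e-9)")
  if (any(residue_freqs < 0)) abort("`residue_freqs` must be non-negative")
  for (m in motifs) {
    if (!all(chars(m$pattern) %in% alphabet))
      abort("planted motifs may only use alphabet characters")
    check_fraction(m$prob, "motif insertion probability")
  }
  length_range <- as.integer(length_range)
  if (length(length_range) != 2 || length_range[1] < 1 || length_range[1] > length_range[2])
    abort("`length_range` must satisfy 1 <= min_len <= max_len")
  structure(
    list(class_label = class_label, residue_freqs = residue_freqs,
         motifs = motifs, length_range = length_range),
    class = "class_profile"
  )
}

#' Default two-class benchmark profiles
#'
#' Class `"algal"` is enriched in Q/A/R and class `"bacterial"` in G/S/L,
#' mirroring the glutamine/glycine-dominated usage contrast seen between
#' algal and bacterial proteomes; the enrichment magnitude is configurable.
#'
#' @param contrast Per-residue probability given to each of the three
#'   enriched residues of a class (default 0.12, a strong contrast).
#' @param length_range Passed to [class_profile()].
#' @return Named list with elements `algal` and `bacterial`.
#' @export
default_profiles <- function(contrast = 0.12, length_range = c(150L, 450L)) {
  list(
    algal = class_profile("algal",
                          enrich = stats::setNames(rep(contrast, 3), c("Q", "A", "R")),
                          length_range = length_range),
    bacterial = class_profile("bacterial",
                              enrich = stats::setNames(rep(contrast, 3), c("G", "S", "L")),
                              length_range = length_range)
  )
}

#' Read class profiles from a YAML or JSON specification
#'
#' The file holds a list of profile specs, each with fields `class_label`
#' and optionally `residue_freqs` (named map), `enrich` (named map),
#' `motifs` (list of `{pattern, prob}`), `length_range` (two integers), and
#' `x_prob` — the arguments of [class_profile()].
#'
#' @param path Path to a `.yaml`/`.yml` (requires the yaml package) or
#'   `.json` file.
#' @return Named list of [class_profile()] objects (names = class labels).
#' @export
read_profiles <- function(path) {
  spec <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort("reading YAML profiles requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  profiles <- lapply(spec, function(p) {
    args <- list(class_label = p$class_label)
    if (!is.null(p$residue_freqs)) args$residue_freqs <- unlist(p$residue_freqs)
    if (!is.null(p$enrich)) args$enrich <- unlist(p$enrich)
    if (!is.null(p$motifs))
      args$motifs <- lapply(p$motifs, function(m) list(pattern = m$pattern,
                                                      prob = m$prob))
    if (!is.null(p$length_range)) args$length_range <- unlist(p$length_range)
    if (!is.null(p$x_prob)) args$x_prob <- p$x_prob
    do.call(class_profile, args)
  })
  stats::setNames(profiles, vapply(profiles, `[[`, character(1), "class_label"))
}

#' Generate a synthetic proteome from a class profile
#'
#' Sequence lengths are uniform over the profile's length range; residues are
#' drawn i.i.d. from the profile's residue frequencies. Each planted motif is
#' inserted with its per-sequence probability at a uniformly chosen position,
#' overwriting the residues there so the configured length distribution is
#' untouched. Identical `(profile, n_seqs, seed)` triples reproduce
#' byte-identical output.
#'
#' @param profile A [class_profile()].
#' @param n_seqs Number of sequences (>= 0).
#' @param seed Integer seed; all randomness is local to the call.
#' @param id_prefix Prefix for record ids (default the class label).
#' @return Tibble with columns `id`, `sequence`, `class`.
#' @examples
#' generate_proteome(default_profiles()$algal, n_seqs = 2, seed = 1)
#' @export
generate_proteome <- function(profile, n_seqs, seed, id_prefix = NULL) {
  if (!inherits(profile, "class_profile")) abort("`profile` must be a class_profile")
  if (n_seqs < 0) abort("`n_seqs` must be >= 0")
  if (is.null(id_prefix)) id_prefix <- profile$class_label
  if (n_seqs == 0) {
    return(tibble::tibble(id = character(), sequence = character(), class = character()))
  }
  alphabet <- names(profile$residue_freqs)
  withr::with_seed(seed, {
    lens <- sample(seq(profile$length_range[1], profile$length_range[2]),
                   n_seqs, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      s <- sample(alphabet, L, replace = TRUE, prob = profile$residue_freqs)
      for (m in profile$motifs) {
        k <- nchar(m$pattern)
        if (k <= L && stats::runif(1) < m$prob) {
          at <- sample.int(L - k + 1L, 1L)
          s[at:(at + k - 1L)] <- chars(m$pattern)
        }
      }
      paste(s, collapse = "")
    }, character(1))
  })
  tibble::tibble(
    id = sprintf("%s_%05d", id_prefix, seq_len(n_seqs)),
    sequence = seqs,
    class = profile$class_label
  )
}

#' Generate a labelled two-class benchmark corpus
#'
#' Convenience wrapper producing equally sized proteomes for two profiles
#' with distinct class labels, the synthetic stand-in for a paired
#' target/contaminant training corpus.
#'
#' @param profile_a,profile_b [class_profile()] objects with distinct labels.
#' @param n_per_class Sequences per class.
#' @param seed Integer seed; the two classes use derived sub-seeds.
#' @return Tibble with `id`, `sequence`, `class` (both classes, A first).
#' @export
make_benchmark_pair <- function(profile_a, profile_b, n_per_class, seed) {
  if (identical(profile_a$class_label, profile_b$class_label))
    abort("profiles must carry distinct class labels")
  dplyr::bind_rows(
    generate_proteome(profile_a, n_per_class, seed = seed),
    generate_proteome(profile_b, n_per_class, seed = seed + 1L)
  )
}
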