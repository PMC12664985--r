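#' Build the default TI-free synthetic benchmark
#'
#' End-to-end construction of the standard two-class benchmark used
#' throughout the package's examples and validation: synthetic proteomes
#' from [default_profiles()] (or any two profiles), per-class unisequence
#' concatenation, fixed-length fragmentation, pool truncation to exactly
#' `n_per_class` fragments, and balanced assembly into shuffled
#' train/eval/test splits.
#'
#' @param n_per_class Fragments per class after truncation (default 2500,
#'   giving ~2000 training fragments per class under the default splits).
#' @param seed Integer seed for generation, shuffling and splitting.
#' @param profiles List of two [class_profile()]s (default
#'   [default_profiles()]).
#' @param frag_len Fragment length in residues (default 100).
#' @param splits Split fractions for [assemble_tifree()].
#' @return List with `data` (tibble: text, label, split), `profiles`, and
#'   `n_source_seqs` (proteome sizes used).
#' @export
tifree_benchmark <- function(n_per_class = 2500L, seed = 1L,
                             profiles = default_profiles(), frag_len = 100L,
                             splits = c(train = 0.8, eval = 0.1, test = 0.1)) {
  if (length(profiles) != 2) abort("`profiles` must hold two class profiles")
  mean_len <- mean(vapply(profiles, function(p) mean(p$length_range), numeric(1)))
  # overshoot the proteome size so each pool exceeds n_per_class fragments
  n_seqs <- ceiling(n_per_class * frag_len / mean_len * 1.15)
  pools <- lapply(seq_along(profiles), function(i) {
    rec <- generate_proteome(profiles[[i]], n_seqs, seed = seed + i)
    frags <- fragment_unisequence(build_unisequence(rec), frag_len)
    if (length(frags) < n_per_class)
      abort("proteome too small for the requested fragment count")
    frags[seq_len(n_per_class)]
  })
  names(pools) <- vapply(profiles, `[[`, character(1), "class_label")
  list(data = assemble_tifree(pools, seed = seed, splits = splits),
       profiles = profiles, n_source_seqs = n_seqs)
}
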