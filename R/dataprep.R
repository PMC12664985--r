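#' Concatenate records into one continuous unisequence
#'
#' Joins all sequences in input order with headers and line breaks removed,
#' destroying gene boundaries. Fragmenting the result yields chimeric,
#' terminal-information-free training units; build one unisequence per class
#' so fragment labels stay unambiguous.
#'
#' @param records Tibble with a `sequence` column (or a character vector).
#' @return Single string; its length is the sum of record lengths.
#' @export
build_unisequence <- function(records) {
  seqs <- if (is.character(records)) records else records$sequence
  if (length(seqs) == 0) abort("cannot build a unisequence from zero records")
  paste(seqs, collapse = "")
}

#' Cut a unisequence into fixed-length fragments
#'
#' Returns `floor(L / frag_len)` fragments of exactly `frag_len` residues
#' covering the unisequence prefix in order; the trailing remainder shorter
#' than `frag_len` is discarded, never padded, so every fragment has
#' identical length and length carries no class signal.
#'
#' @param unisequence Single string.
#' @param frag_len Fragment length in residues (default 100).
#' @return Character vector of fragments (possibly empty).
#' @export
fragment_unisequence <- function(unisequence, frag_len = 100L) {
  if (frag_len < 1) abort("`frag_len` must be >= 1")
  L <- nchar(unisequence)
  n <- L %/% frag_len
  if (n == 0) return(character(0))
  starts <- (seq_len(n) - 1L) * frag_len + 1L
  substring(unisequence, starts, starts + frag_len - 1L)
}

#' Assemble a balanced, shuffled, split TI-free dataset
#'
#' Labels fragments by their source class, downsamples every larger pool
#' (seeded, without replacement) to the smallest so all classes are equally
#' represented, shuffles the combined pool, and partitions it by the split
#' fractions. Works for two or more classes.
#'
#' @param frag_pools Named list of character vectors, one element per class;
#'   names are the class labels. All pools must be non-empty.
#' @param seed Integer seed controlling downsampling, shuffle, and split.
#' @param splits Named fractions summing to 1; default
#'   `c(train = .8, eval = .1, test = .1)`. Split sizes are
#'   `floor(cumsum(splits) * n)` differences so every item lands in exactly
#'   one split.
#' @return Tibble with columns `text`, `label`, `split`.
#' @export
assemble_tifree <- function(frag_pools, seed,
                            splits = c(train = 0.8, eval = 0.1, test = 0.1)) {
  if (is.null(names(frag_pools)) || any(!nzchar(names(frag_pools))))
    abort("`frag_pools` must be a named list (names = class labels)")
  sizes <- lengths(frag_pools)
  if (any(sizes == 0))
    abort(paste0("empty fragment pool for class: ",
                 toString(names(frag_pools)[sizes == 0])))
  if (abs(sum(splits) - 1) > 1e-9) abort("`splits` must sum to 1")
  n_keep <- min(sizes)
  withr::with_seed(seed, {
    kept <- lapply(frag_pools, function(p) {
      if (length(p) > n_keep) p[sort(sample.int(length(p), n_keep))] else p
    })
    ds <- tibble::tibble(
      text = unlist(kept, use.names = FALSE),
      label = rep(names(kept), each = n_keep)
    )
    ds <- ds[sample.int(nrow(ds)), ]
  })
  bounds <- floor(cumsum(splits) * nrow(ds))
  ds$split <- rep(names(splits), times = diff(c(0L, bounds)))
  ds
}

#' Build tag-suffixed training strings for full-length sequences
#'
#' Appends `"<"` and the class tag to each sequence; the `"<"` delimiter
#' marks where the model switches from sequence modelling to label emission.
#'
#' @param records Tibble with `id`, `sequence`, `class` columns.
#' @param tag_map Named character vector mapping class label to tag string.
#' @return Tibble with columns `id`, `text` (sequence + `"<"` + tag), `label`.
#' @export
prep_tiinclusive <- function(records, tag_map) {
  if (any(!nzchar(records$sequence))) {
    abort(paste0("empty sequences for ids: ",
                 toString(records$id[!nzchar(records$sequence)])))
  }
  missing <- is.na(records$class) | !(records$class %in% names(tag_map))
  if (any(missing)) {
    abort(paste0("records with missing/unknown class: ",
                 toString(utils::head(records$id[missing], 10))))
  }
  tibble::tibble(
    id = records$id,
    text = paste0(records$sequence, "<", unname(tag_map[records$class])),
    label = records$class
  )
}

#' Remove exact-duplicate items from a holdout set
#'
#' Fixed-string whole-item matching on the bare fragment/sequence strings:
#' any holdout item whose text exactly equals a training item is removed.
#' The screen is idempotent.
#'
#' @param holdout,train Tibbles with a `text` column.
#' @return List with `holdout` (cleaned tibble) and `report`, a one-row
#'   tibble with `n_before`, `n_overlap`, `n_after` and a list-column
#'   `removed_idx` of removed holdout row indices.
#' @export
dedup_screen <- function(holdout, train) {
  dup <- holdout$text %in% train$text
  list(
    holdout = holdout[!dup, ],
    report = tibble::tibble(
      n_before = nrow(holdout),
      n_overlap = sum(dup),
      n_after = nrow(holdout) - sum(dup),
      removed_idx = list(which(dup))
    )
  )
}
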