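#' Build a character-level vocabulary
#'
#' Pure character-level encoding: the 20 canonical residues, the ambiguity
#' code `"X"`, one single-character tag token per class, the `"<"` delimiter
#' and a reserved pad token. Tags default to the digits `"0", "1", ...` in
#' class order, characters guaranteed to lie outside the residue alphabet.
#' Non-canonical residue codes (B, Z, J, U, O, `"?"`, ...) encode as `"X"`.
#'
#' @param classes Character vector of class labels, in the configured order
#'   (the order also fixes deterministic tie-breaking at prediction time).
#' @param tags Optional character vector of single-character tags, parallel
#'   to `classes`.
#' @return Object of class `aa_vocab`: list with `tokens`, `pad`, `delim`,
#'   `tag_map` (class -> tag), `classes`.
#' @export
aa_vocabulary <- function(classes, tags = NULL) {
  if (length(classes) < 1) abort("need at least one class")
  if (anyDuplicated(classes)) abort("class labels must be distinct")
  if (is.null(tags)) tags <- as.character(seq_along(classes) - 1L)
  if (length(tags) != length(classes) || any(nchar(tags) != 1))
    abort("`tags` must be single characters, one per class")
  if (any(tags %in% c(AA_ALPHABET20, "X", "<", "_")))
    abort("tags must not collide with residue, delimiter, or pad tokens")
  tokens <- c(AA_ALPHABET20, "X", tags, "<", "_")
  structure(
    list(tokens = tokens, pad = "_", delim = "<",
         tag_map = stats::setNames(tags, classes), classes = classes),
    class = "aa_vocab"
  )
}

vocab_size <- function(vocab) length(vocab$tokens)
pad_id <- function(vocab) match(vocab$pad, vocab$tokens)
tag_ids <- function(vocab) match(unname(vocab$tag_map), vocab$tokens)

#' Encode text as token ids
#'
#' Characters missing from the vocabulary map to the `"X"` ambiguity token.
#' Output is right-padded with the pad token up to `pad_to`.
#'
#' @param text Single string.
#' @param vocab An [aa_vocabulary()].
#' @param pad_to Target length; `NULL` means no padding. Text longer than
#'   `pad_to` is an error (fixed-length mode).
#' @return Integer vector of token ids (1-based).
#' @export
encode_text <- function(text, vocab, pad_to = NULL) {
  cc <- chars(text)
  ids <- match(cc, vocab$tokens)
  ids[is.na(ids)] <- match("X", vocab$tokens)
  if (!is.null(pad_to)) {
    if (length(ids) > pad_to)
      abort(sprintf("text of length %d exceeds pad_to = %d", length(ids), pad_to))
    ids <- c(ids, rep(pad_id(vocab), pad_to - length(ids)))
  }
  ids
}

#' Decode token ids back to text
#'
#' @param ids Integer token ids.
#' @param vocab An [aa_vocabulary()].
#' @param strip_pad Drop trailing pad tokens (default TRUE).
#' @return Single string.
#' @export
decode_ids <- function(ids, vocab, strip_pad = TRUE) {
  if (any(ids < 1 | ids > vocab_size(vocab))) abort("token id out of range")
  if (strip_pad) ids <- ids[ids != pad_id(vocab)]
  paste(vocab$tokens[ids], collapse = "")
}
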