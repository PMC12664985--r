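#' Write sequence records to FASTA
#'
#' Headers are `<id> class=<label>` when a class column is present, and
#' sequences are wrapped at 60 columns.
#'
#' @param records Tibble with columns `id`, `sequence` and optionally `class`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (!all(c("id", "sequence") %in% names(records)))
    abort("`records` needs `id` and `sequence` columns")
  if (anyDuplicated(records$id)) abort("record ids must be unique")
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- if ("class" %in% names(records)) {
    paste0(records$id, " class=", records$class)
  } else {
    records$id
  }
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Sequences are upper-cased and `*` stop codons stripped. A `class=<label>`
#' token in the header, as written by [write_fasta()], is parsed into the
#' `class` column (NA when absent).
#'
#' @param path FASTA file path.
#' @return Tibble with columns `id`, `sequence`, `class`.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) abort(paste0("could not read FASTA '", path, "': ", conditionMessage(e)))
  )
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  cls <- ifelse(grepl("class=\\S+", headers),
                sub(".*class=(\\S+).*", "\\1", headers), NA_character_)
  seqs <- toupper(gsub("*", "", as.character(set), fixed = TRUE))
  tibble::tibble(id = ids, sequence = unname(seqs), class = cls)
}
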