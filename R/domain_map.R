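#' Scan motifs against a domain database
#'
#' Counts occurrences of each motif pattern in every database sequence,
#' overlapping matches included (lookahead scanning), and aggregates counts
#' per (motif, domain accession). `"X"` in a pattern matches any single
#' residue. Accessions are parsed from headers as the first token matching
#' `PF\\d{5}` (an optional version suffix is stripped before aggregation),
#' falling back to the first whitespace-delimited header token; records
#' whose header yields no token are skipped and counted in the `n_skipped`
#' attribute.
#'
#' @param motifs Tibble with `pattern` and `mean_score` columns (e.g.
#'   aggregated output of the motif miners).
#' @param domain_db FASTA file path or tibble with `id` (header) and
#'   `sequence` columns.
#' @return Tibble: `motif`, `accession`, `count` (>= 1; zero-count pairs are
#'   suppressed), `mean_score`; attribute `n_skipped`.
#' @export
scan_motifs <- function(motifs, domain_db) {
  if (!all(c("pattern", "mean_score") %in% names(motifs)))
    abort("`motifs` needs `pattern` and `mean_score` columns")
  db <- if (is.character(domain_db)) {
    set <- Biostrings::readAAStringSet(domain_db)
    tibble::tibble(id = names(set), sequence = as.character(set))
  } else {
    domain_db
  }
  acc <- parse_accession(db$id)
  skipped <- is.na(acc)
  db <- db[!skipped, , drop = FALSE]
  acc <- acc[!skipped]

  rows <- lapply(seq_len(nrow(motifs)), function(i) {
    pat <- motifs$pattern[i]
    rx <- paste0("(?=", gsub("X", ".", pat, fixed = TRUE), ")")
    hits <- vapply(db$sequence, function(s) {
      m <- gregexpr(rx, s, perl = TRUE)[[1]]
      if (m[1] == -1) 0L else length(m)
    }, integer(1), USE.NAMES = FALSE)
    if (all(hits == 0)) return(NULL)
    counts <- rowsum(hits, acc)
    keep <- counts[, 1] > 0
    tibble::tibble(motif = pat, accession = rownames(counts)[keep],
                   count = as.integer(counts[keep, 1]),
                   mean_score = motifs$mean_score[i])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble::tibble(motif = character(), accession = character(),
                          count = integer(), mean_score = numeric())
  attr(out, "n_skipped") <- sum(skipped)
  out
}

parse_accession <- function(headers) {
  pf <- regmatches(headers, regexpr("PF\\d{5}(\\.\\d+)?", headers))
  out <- character(length(headers))
  has_pf <- grepl("PF\\d{5}", headers)
  out[has_pf] <- sub("\\.\\d+$", "", regmatches(headers, regexpr("PF\\d{5}(\\.\\d+)?", headers)))
  first_tok <- sub("\\s.*$", "", headers)
  out[!has_pf] <- first_tok[!has_pf]
  out[!nzchar(out)] <- NA_character_
  out
}

#' Append the weighted relevance score and rank associations
#'
#' The weighted score of a motif-domain pair is `count * mean_score`: high
#' when the motif is both salient to the model and recurrent in that
#' domain's sequences. Rows are sorted by weighted score descending, ties
#' broken by count (descending) then motif (lexicographic) for a stable,
#' reproducible ranking.
#'
#' @param table Association tibble from [scan_motifs()].
#' @return The table with `weighted_score` appended, sorted.
#' @export
score_and_rank <- function(table) {
  if (any(table$count < 1)) abort("counts must be >= 1")
  if (any(!is.finite(table$mean_score))) abort("scores must be finite")
  out <- dplyr::mutate(table, weighted_score = .data$count * .data$mean_score)
  dplyr::arrange(out, dplyr::desc(.data$weighted_score),
                 dplyr::desc(.data$count), .data$motif)
}

#' Unique domain accessions among the top-ranked associations
#'
#' How far the highest-scoring motif-domain pairs collapse onto few
#' domains: the distinct accessions among the top `k` rows of a ranked
#' association table.
#'
#' @param table Ranked association tibble from [score_and_rank()].
#' @param k Number of top rows to inspect; values beyond the table size use
#'   all rows.
#' @return Character vector of distinct accessions, in rank order.
#' @export
top_k_unique_domains <- function(table, k) {
  k <- min(k, nrow(table))
  unique(table$accession[seq_len(k)])
}
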