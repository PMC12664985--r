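mini_db <- function() {
  tibble::tibble(
    id = c("seq1 PF00001.21;dom_one;", "seq2 PF00001.21;dom_one;",
           "seq3 PF00002.3;dom_two;", "seq4 PF00003.1;dom_three;"),
    sequence = c("MKACDAAAKL", "ACDPPACDW", "AAAA", "ABAQACAW")
  )
}

test_that("motif scanning counts overlapping and degenerate matches", {
  motifs <- tibble::tibble(pattern = c("ACD", "AAA", "AXA"),
                           mean_score = c(0.5, 0.9, 0.2))
  tab <- scan_motifs(motifs, mini_db())

  # "ACD" occurs once in seq1 and twice in seq2, all under PF00001
  expect_equal(tab$count[tab$motif == "ACD" & tab$accession == "PF00001"], 3)
  # "AAA" in "AAAA" counts both overlapping occurrences
  expect_equal(tab$count[tab$motif == "AAA" & tab$accession == "PF00002"], 2)
  # degenerate X matches any residue: ABA and ACA both hit
  expect_gte(tab$count[tab$motif == "AXA" & tab$accession == "PF00003"], 2)
  # zero-count pairs are suppressed
  expect_false(any(tab$motif == "ACD" & tab$accession == "PF00003"))
  expect_true(all(tab$count >= 1))
})

test_that("doubling a sequence's copies doubles that accession's counts", {
  motifs <- tibble::tibble(pattern = "ACD", mean_score = 1)
  db <- mini_db()
  tab1 <- scan_motifs(motifs, db)
  db2 <- dplyr::bind_rows(db, db[db$id == "seq2 PF00001.21;dom_one;", ])
  tab2 <- scan_motifs(motifs, db2)
  c1 <- tab1$count[tab1$accession == "PF00001"]
  expect_equal(tab2$count[tab2$accession == "PF00001"], c1 + 2)
})

test_that("weighted scoring, ranking and tie-breaks are exact", {
  tab <- tibble::tibble(
    motif = c("AAA", "CCC", "DDD", "BBB"),
    accession = c("PF1", "PF2", "PF3", "PF4"),
    count = c(10L, 8L, 2L, 4L),
    mean_score = c(0.5, 0.5, 2.0, 1.0)
  )
  ranked <- score_and_rank(tab)
  expect_equal(ranked$weighted_score, c(5, 4, 4, 4))
  # weighted_score == count * mean_score exactly
  expect_identical(ranked$weighted_score, ranked$count * ranked$mean_score)
  # ties: higher count first, then lexicographic motif
  expect_equal(ranked$motif, c("AAA", "CCC", "BBB", "DDD"))
  # ranking permutes rows and appends one column
  expect_setequal(ranked$motif, tab$motif)
  expect_equal(ncol(ranked), ncol(tab) + 1)
  expect_error(score_and_rank(dplyr::mutate(tab, count = c(0L, 1L, 1L, 1L))),
               ">= 1")
})

test_that("top-k unique accessions deduplicate and saturate", {
  tab <- tibble::tibble(accession = c("PF1", "PF1", "PF2", "PF1", "PF3"))
  expect_equal(top_k_unique_domains(tab, 2), "PF1")
  expect_equal(top_k_unique_domains(tab, 0), character(0))
  expect_setequal(top_k_unique_domains(tab, 100), c("PF1", "PF2", "PF3"))
})

test_that("scanning a FASTA file and parsing headerless accessions", {
  db <- mini_db()
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(unlist(Map(function(h, s) c(paste0(">", h), s), db$id, db$sequence)),
             path)
  tab <- scan_motifs(tibble::tibble(pattern = "ACD", mean_score = 1), path)
  expect_equal(sum(tab$count), 3)
  # headers without a PF accession fall back to the first token
  tab2 <- scan_motifs(tibble::tibble(pattern = "AAAA", mean_score = 1),
                      tibble::tibble(id = "plain_header some description",
                                     sequence = "AAAA"))
  expect_equal(tab2$accession, "plain_header")
})
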