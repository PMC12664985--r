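test_that("unisequence concatenation preserves order and length", {
  expect_equal(build_unisequence(tibble::tibble(sequence = c("MK", "VL"))), "MKVL")
  expect_equal(build_unisequence("SINGLE"), "SINGLE")
  recs <- tibble::tibble(sequence = strrep(c("A", "C", "D"), c(70, 80, 90)))
  expect_equal(nchar(build_unisequence(recs)), 240)
  expect_error(build_unisequence(tibble::tibble(sequence = character())), "zero")
})

test_that("fragmentation follows the floor rule and discards the remainder", {
  u <- strrep("ACDEFGHIKL", 25)                       # L = 250
  fr <- fragment_unisequence(u, 100)
  expect_length(fr, 2)
  expect_true(all(nchar(fr) == 100))
  expect_equal(paste(fr, collapse = ""), substr(u, 1, 200))

  expect_equal(fragment_unisequence(strrep("A", 100), 100), strrep("A", 100))
  expect_length(fragment_unisequence(strrep("A", 99), 100), 0)
  expect_length(fragment_unisequence("", 100), 0)
  expect_error(fragment_unisequence("AC", 0), ">= 1")
})

test_that("fragment count times length plus remainder conserves total length", {
  withr::with_seed(31, {
    for (i in 1:20) {
      L <- sample(0:557, 1)
      l <- sample(c(7, 50, 100), 1)
      u <- paste(sample(AA_ALPHABET20, L, replace = TRUE), collapse = "")
      fr <- fragment_unisequence(u, l)
      expect_length(fr, L %/% l)
      expect_equal(length(fr) * l + L %% l, L)
      if (length(fr)) expect_equal(paste(fr, collapse = ""), substr(u, 1, (L %/% l) * l))
    }
  })
})

test_that("assembly balances classes, shuffles reproducibly, and partitions", {
  pools <- list(a = replicate(150, paste(sample(AA_ALPHABET20, 10, TRUE), collapse = "")),
                b = replicate(100, paste(sample(AA_ALPHABET20, 10, TRUE), collapse = "")))
  ds <- assemble_tifree(pools, seed = 3)
  expect_equal(as.integer(table(ds$label)), c(100L, 100L))
  expect_true(all(ds$text[ds$label == "a"] %in% pools$a))        # subsample, no invention
  expect_identical(ds, assemble_tifree(pools, seed = 3))
  expect_false(identical(ds$text, assemble_tifree(pools, seed = 4)$text))
  # permutation: the multiset of retained items is preserved across the shuffle
  expect_setequal(ds$text[ds$label == "b"], pools$b)
  expect_equal(as.integer(table(ds$split)[c("train", "eval", "test")]), c(160L, 20L, 20L))
  expect_error(assemble_tifree(list(a = character(), b = "AC"), seed = 1), "empty")
  expect_error(assemble_tifree(pools, seed = 1, splits = c(train = .5, test = .4)),
               "sum to 1")
})

test_that("tag suffixing round-trips and validates classes", {
  rec <- tibble::tibble(id = c("r1", "r2"), sequence = c("MKV", "ACDE"),
                        class = c("algal", "bacterial"))
  out <- prep_tiinclusive(rec, c(algal = "0", bacterial = "1"))
  expect_equal(out$text, c("MKV<0", "ACDE<1"))
  expect_equal(sub("<[^<]*$", "", out$text), rec$sequence)

  expect_error(prep_tiinclusive(tibble::tibble(id = "r", sequence = "MK", class = "viral"),
                                c(algal = "0")), "viral|unknown")
  expect_error(prep_tiinclusive(tibble::tibble(id = "r", sequence = "", class = "algal"),
                                c(algal = "0")), "empty")
})

test_that("dedup removes exactly the planted duplicates and is idempotent", {
  train <- tibble::tibble(text = c("AAA", "CCC", "DDD"), label = "a")
  holdout <- tibble::tibble(text = c("AAA", "EEE", "CCC", "CCD"), label = "a")
  res <- dedup_screen(holdout, train)
  expect_equal(res$report$n_overlap, 2)
  expect_equal(res$report$n_after, res$report$n_before - res$report$n_overlap)
  expect_equal(res$holdout$text, c("EEE", "CCD"))    # one-residue difference retained
  again <- dedup_screen(res$holdout, train)
  expect_equal(again$report$n_overlap, 0)
  expect_identical(again$holdout, res$holdout)
})
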