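test_that("generation is seeded, sized, and validated", {
  prof <- default_profiles()$algal
  expect_equal(nrow(generate_proteome(prof, 0, seed = 1)), 0)

  a <- generate_proteome(prof, 20, seed = 42)
  b <- generate_proteome(prof, 20, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a$sequence, generate_proteome(prof, 20, seed = 43)$sequence))

  expect_equal(nrow(a), 20)
  expect_true(all(nchar(a$sequence) >= prof$length_range[1]))
  expect_true(all(nchar(a$sequence) <= prof$length_range[2]))
  expect_false(anyDuplicated(a$id) > 0)
  expect_true(all(strsplit(paste(a$sequence, collapse = ""), "")[[1]] %in%
                    c(AA_ALPHABET20, "X")))

  expect_error(class_profile("bad", residue_freqs = c(A = 0.5, C = 0.4)),
               "sum to 1")
  expect_error(class_profile(""), "non-empty")
  expect_error(class_profile("x", length_range = c(5, 2)), "min_len")
})

test_that("empirical residue frequencies converge to the profile", {
  # binomial sampling at n = 500 * 200 = 100,000 residues: sd of the
  # glycine frequency is sqrt(.3*.7/1e5) ~ 0.0014, so +/-0.02 is ~14 sd
  freqs <- c(stats::setNames(rep(0.7 / 19, 19), setdiff(AA_ALPHABET20, "G")),
             G = 0.3, X = 0)
  prof <- class_profile("g30", residue_freqs = freqs, length_range = c(200, 200))
  rec <- generate_proteome(prof, 500, seed = 9)
  cc <- strsplit(paste(rec$sequence, collapse = ""), "")[[1]]
  expect_equal(mean(cc == "G"), 0.3, tolerance = 0.02 / 0.3)
})

test_that("planted motifs appear verbatim at the configured rate", {
  prof <- class_profile("m", motifs = list(list(pattern = "WWWHHWWW", prob = 1)),
                        length_range = c(60, 80))
  rec <- generate_proteome(prof, 40, seed = 3)
  expect_true(all(grepl("WWWHHWWW", rec$sequence, fixed = TRUE)))
  expect_true(all(nchar(rec$sequence) <= 80))    # overwrite, not splice

  prof0 <- class_profile("m0", motifs = list(list(pattern = "WWWHHWWW", prob = 0)),
                         length_range = c(60, 80))
  rec0 <- generate_proteome(prof0, 40, seed = 3)
  expect_false(any(grepl("WWWHHWWW", rec0$sequence, fixed = TRUE)))
})

test_that("benchmark pairs are labelled, sized, and label-distinct", {
  prof <- default_profiles()
  pair <- make_benchmark_pair(prof$algal, prof$bacterial, 10, seed = 1)
  expect_equal(as.integer(table(pair$class)[c("algal", "bacterial")]), c(10L, 10L))
  expect_error(make_benchmark_pair(prof$algal, prof$algal, 5, seed = 1),
               "distinct")
})

test_that("the default benchmark builder yields balanced splits", {
  bench <- tifree_benchmark(n_per_class = 60, seed = 2)
  ds <- bench$data
  expect_equal(nrow(ds), 120)
  expect_equal(as.integer(table(ds$label)), c(60L, 60L))
  expect_true(all(nchar(ds$text) == 100))
  expect_setequal(unique(ds$split), c("train", "eval", "test"))
})

test_that("profiles round-trip through YAML and JSON specifications", {
  spec <- list(
    list(class_label = "algal", enrich = list(Q = 0.12, A = 0.12, R = 0.12),
         length_range = c(100, 200),
         motifs = list(list(pattern = "WWHH", prob = 0.5))),
    list(class_label = "bacterial", enrich = list(G = 0.12, S = 0.12, L = 0.12))
  )
  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(spec, jpath, auto_unbox = TRUE, digits = NA)
  pj <- read_profiles(jpath)
  expect_named(pj, c("algal", "bacterial"))
  expect_equal(unname(pj$algal$residue_freqs["Q"]), 0.12)
  expect_equal(pj$algal$length_range, c(100L, 200L))
  expect_equal(pj$algal$motifs[[1]]$pattern, "WWHH")

  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(spec, ypath)
  py <- read_profiles(ypath)
  expect_equal(py$algal$residue_freqs, pj$algal$residue_freqs)
})
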