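test_that("influence profiles follow the mean-deviation L2 definition", {
  # identical positions in a layer: zero influence everywhere
  H <- matrix(1, 5, 4)
  pr <- influence_profile(list(H))
  expect_equal(pr$per_layer[1, ], rep(0, 5))
  expect_equal(pr$avg_influence, rep(0, 5))

  # one outlier at distance r from the common point: raw influence r(n-1)/n
  n <- 6; r <- 3
  H2 <- matrix(0, n, 3)
  H2[4, 1] <- r
  pr2 <- influence_profile(list(H2))
  expect_equal(pr2$per_layer[1, 4], r * (n - 1) / n, tolerance = 1e-12)
  expect_equal(pr2$per_layer[1, 1], r / n, tolerance = 1e-12)
  # min-max normalization pins the extremes
  expect_equal(max(pr2$avg_influence), 1)
  expect_equal(min(pr2$avg_influence), 0)

  expect_error(influence_profile(list()), "at least one layer")
  expect_error(influence_profile(list(matrix(0, 3, 2), matrix(0, 4, 2))),
               "position count")
})

test_that("class separation distances and seeds follow their definitions", {
  # all embeddings identical: I = 0 everywhere, no seeds
  emb <- replicate(4, matrix(1, 3, 2), simplify = FALSE)
  seqs <- c("AAC", "ACA", "CAA", "CCA")
  cs <- class_separation(emb, seqs)
  expect_true(all(cs$I[!is.na(cs$I)] == 0))
  expect_equal(nrow(cs$seeds), 0)

  # residue A always embeds at u, others at v: I(a, i) = ||u - v||
  u <- c(2, 0); v <- c(0, 1)
  emb2 <- lapply(seqs, function(s) {
    t(vapply(strsplit(s, "")[[1]],
             function(a) if (a == "A") u else v, numeric(2)))
  })
  cs2 <- class_separation(emb2, seqs)
  expect_equal(unname(cs2$I["A", ]), rep(sqrt(sum((u - v)^2)), 3))

  # percentile threshold uses linear interpolation between closest ranks
  expect_equal(pt_ns$pctl(1:100, 95), 95.05)

  # seeds equivariance: permuting the corpus permutes seq indices
  perm <- c(3, 1, 4, 2)
  cs3 <- class_separation(emb2[perm], seqs[perm])
  m1 <- with(cs2$seeds, sort(paste(seqs[seq_index], position)))
  m2 <- with(cs3$seeds, sort(paste(seqs[perm][seq_index], position)))
  expect_equal(m1, m2)
})

test_that("flexible motif mining finds, masks, prunes and merges peaks", {
  # constant profile: no peaks, no motifs
  expect_equal(nrow(flexible_motifs(rep(0.5, 60), strrep("A", 60))), 0)

  # single sharp multi-residue peak over a noisy sub-threshold background
  withr::with_seed(71, prof <- runif(60, 0, 0.3))
  prof[30:31] <- c(1, 0.9)
  seqc <- strrep("ACDEF", 12)
  mot <- flexible_motifs(prof, seqc, window_size = 5)
  expect_equal(nrow(mot), 1)
  expect_true(mot$start <= 30 && 30 <= mot$start + mot$length - 1)
  expect_true(grepl("X", mot$pattern))                  # below-threshold masking
  expect_equal(nchar(mot$pattern), mot$length)

  # two peaks 3 apart with min distance 5: the lower one is suppressed
  p2 <- rep(0, 40)
  p2[20] <- 1; p2[21] <- 0.98                            # second residue above thr
  p2[23] <- 0.95                                         # lower nearby peak
  pk <- find_peaks(p2, height = 0.5, distance = 5)
  expect_equal(pk, 20)

  # monotone rescaling leaves the motif set unchanged (percentile threshold)
  mot2 <- flexible_motifs(prof * 7 + 2, seqc, window_size = 5)
  expect_equal(mot2$pattern, mot$pattern)
  expect_equal(mot2$start, mot$start)

  # merged motifs never overlap pairwise
  p3 <- rep(0, 80)
  p3[c(20, 21, 24, 25, 50, 51)] <- c(1, .97, .96, .99, .95, .94)
  m3 <- flexible_motifs(p3, strrep("A", 80), window_size = 4, percentile = 90)
  if (nrow(m3) > 1) {
    ends <- m3$start + m3$length - 1
    o <- order(m3$start)
    expect_true(all(m3$start[o][-1] > ends[o][-nrow(m3)]))
  }
})

test_that("strict motifs honour the composite weights and coverage rule", {
  L <- 40
  seqc <- strrep("ACDEF", 8)
  d <- rep(0, L); a <- rep(0, L); g <- rep(0, L)
  # composite = 0.4*divergence when the other channels are zero...
  d[10] <- 1
  comp <- 0.4 * minmax_norm(d) + 0.3 * minmax_norm(a) + 0.3 * minmax_norm(g)
  expect_equal(comp[10], 0.4)
  # ...and 1.0 where all three channels peak together
  a[10] <- 1; g[10] <- 1
  comp <- 0.4 * minmax_norm(d) + 0.3 * minmax_norm(a) + 0.3 * minmax_norm(g)
  expect_equal(comp[10], 1.0)

  # all-zero channels: no motifs
  expect_equal(nrow(strict_motifs(rep(0, L), rep(0, L), rep(0, L), seqc)), 0)

  # coverage 1 with unit length returns exactly the above-threshold positions
  withr::with_seed(2, { dd <- runif(L); aa <- runif(L); gg <- runif(L) })
  compc <- 0.4 * minmax_norm(dd) + 0.3 * minmax_norm(aa) + 0.3 * minmax_norm(gg)
  thr <- pt_ns$pctl(compc, 95)
  mots <- strict_motifs(dd, aa, gg, seqc, min_len = 1, max_len = 1,
                        coverage = 1.0)
  expect_setequal(mots$start, which(compc > thr))

  # brute-force oracle for the window acceptance rule at lengths 3..5,
  # with a planted high-composite block guaranteeing accepted windows
  dd[20:26] <- 3; aa[20:26] <- 3; gg[20:26] <- 3
  compc <- 0.4 * minmax_norm(dd) + 0.3 * minmax_norm(aa) + 0.3 * minmax_norm(gg)
  # percentile 80 sits below the planted block, so windows inside it pass
  thr <- pt_ns$pctl(compc, 80)
  mots2 <- strict_motifs(dd, aa, gg, seqc, min_len = 3, max_len = 5,
                         percentile = 80, coverage = 0.75)
  oracle <- list()
  for (len in 3:5) for (s in 1:(L - len + 1)) {
    win <- compc[s:(s + len - 1)]
    if (mean(win) > thr && mean(win > thr) >= 0.75)
      oracle[[length(oracle) + 1]] <- c(s, len)
  }
  expect_gt(length(oracle), 0)
  expect_equal(nrow(mots2), length(oracle))
  got <- mots2[order(mots2$start, mots2$length), c("start", "length")]
  want <- do.call(rbind, oracle)
  want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
  expect_equal(unname(as.matrix(got)), unname(want))

  expect_error(strict_motifs(dd[-1], aa, gg, seqc), "length")
})

test_that("self-attention diagonals average layers and heads", {
  fit <- toy_fit()
  sad <- attention_self_diagonal(fit, "QARQARQA")
  raw <- attr(sad, "raw")
  expect_true(all(raw >= 0 & raw <= 1))
  expect_equal(raw[1], 1)                 # softmax over a single visible key
  # hand average over the layers x heads diagonals
  fs <- forward_states(fit, "QARQARQA")
  hand <- rowMeans(do.call(cbind, lapply(fs$attention, function(A) {
    apply(A, 3, diag)
  })))
  expect_equal(raw, hand, tolerance = 1e-12)
  expect_error(attention_self_diagonal(linear_model(), "QA"), "no attention")
})
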