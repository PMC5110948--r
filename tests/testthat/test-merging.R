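test_that("column ALLR is symmetric and anchored at background", {
  f0 <- rep(0.25, 4)
  expect_equal(allr_column(c(10, 10, 10, 10), c(5, 5, 5, 5), f0), 0,
               tolerance = 1e-9)
  set.seed(6)
  for (rep in 1:10) {
    n1 <- sample(0:20, 4, replace = TRUE) + 1
    n2 <- sample(0:20, 4, replace = TRUE) + 1
    expect_equal(allr_column(n1, n2, f0), allr_column(n2, n1, f0))
  }
  # two unanimous identical columns approach ln 4 as smoothing vanishes
  expect_equal(allr_column(c(10, 0, 0, 0), c(10, 0, 0, 0), f0, eps = 0.01),
               log(4), tolerance = 0.01)
})

make_motif_fixture <- function(strings, seqs = NULL, starts = NULL) {
  X <- lmers_of(strings)
  B <- uniform_background()
  eppmotif:::.make_motif(X, seq_along(strings), B)
}

test_that("motif similarity maximizes ALLR over all admissible overlaps", {
  B0 <- uniform_background()
  set.seed(12)
  m1 <- make_motif_fixture(replicate(8, paste0("ACGTAC", rand_dna(2))))
  m2 <- make_motif_fixture(replicate(8, paste0(rand_dna(2), "ACGTAC")))
  ms <- motif_similarity(m1, m2, B0)
  # brute force over all offset pairs with overlap >= 6
  brute <- -Inf
  for (w1 in 1:3) for (w2 in 1:3) {
    ls <- min(8 - w1, 8 - w2) + 1
    if (ls < 6) next
    s <- sum(vapply(0:(ls - 1), function(h)
      allr_column(m1$counts[w1 + h, ], m2$counts[w2 + h, ], B0$f0),
      numeric(1)))
    brute <- max(brute, s)
  }
  expect_equal(ms$sim, brute, tolerance = 1e-9)

  # self-similarity peaks at the full overlap
  self <- motif_similarity(m1, m1, B0)
  expect_equal(self$alignment$w1, 1L)
  expect_equal(self$alignment$w2, 1L)
  expect_equal(self$alignment$length, 8L)
  # disjoint alphabets score below self-similarity
  m3 <- make_motif_fixture(rep("TTTTTTTT", 8))
  expect_lt(motif_similarity(m1, m3, B0)$sim, self$sim)
})

test_that("combining aligned motifs spans the union of their columns", {
  B0 <- uniform_background()
  m1 <- make_motif_fixture(rep("ACGTACGT", 6))
  same <- combine_motifs(m1, m1, list(w1 = 1, w2 = 1, length = 8), B0)
  expect_equal(same$width, 8L)
  expect_equal(same$n_members, m1$n_members)   # duplicated sites collapse
  expect_equal(same$consensus, m1$consensus)

  m2 <- make_motif_fixture(rep("GTACGTAA", 6))
  comb <- combine_motifs(m1, m2, list(w1 = 3, w2 = 1, length = 6), B0)
  expect_equal(comb$width, 10L)                 # 8 and 8 overlapping by 6
  # provenance: every output member comes from an input member
  key <- function(m) paste(m$sites$seq_index, m$sites$start)
  expect_true(all(key(comb) %in% c(key(m1), key(m2))))
})

test_that("the top-u list respects capacity, redundancy and IC order", {
  B0 <- uniform_background()
  set.seed(33)
  strong <- make_motif_fixture(rep("ACGTACGT", 10))
  weak <- make_motif_fixture(c(rep("TTGGCCAA", 6), replicate(4, rand_dna(8))))
  # u = 1 with two dissimilar motifs: the higher-IC one survives
  kept <- maintain_top(list(weak, strong), u = 1, B = B0)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$consensus, strong$consensus)

  # a duplicate is combined, not appended
  kept2 <- maintain_top(list(strong, strong), u = 5, B = B0)
  expect_length(kept2, 1L)
  expect_true(kept2[[1]]$combined)

  # dissimilar motifs all retained, IC-descending
  third <- make_motif_fixture(rep("GGATCCGG", 10))
  kept3 <- maintain_top(list(weak, strong, third), u = 5, B = B0)
  expect_length(kept3, 3L)
  ics <- vapply(kept3, function(m) m$ic, numeric(1))
  expect_true(all(diff(ics) <= 0))
})

test_that("trimming reports the maximum-information fixed-width window", {
  B0 <- uniform_background()
  X <- lmers_of(rep("ACGTACGT", 6))
  m <- eppmotif:::.make_motif(X, 1:6, B0)
  expect_identical(trim_motif(m, 8, X, B0), m)   # nothing to trim

  m2 <- eppmotif:::.make_motif(X, 1:6, B0)
  comb <- combine_motifs(m, m2, list(w1 = 3, w2 = 1, length = 6), B0)
  expect_equal(comb$width, 10L)
  tr <- trim_motif(comb, 8, X, B0)
  expect_equal(tr$width, 8L)
  expect_equal(tr$consensus, "ACGTACGT")
})
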