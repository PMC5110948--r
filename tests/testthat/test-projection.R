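test_that("sequence-model thresholds follow the model semantics", {
  expect_equal(thresholds_for_model("OOPS", 20), list(min_size = 15L, max_size = 20L))
  expect_equal(thresholds_for_model("ZOOPS", 20), list(min_size = 10L, max_size = 20L))
  expect_equal(thresholds_for_model("TCM", 20), list(min_size = 20L, max_size = 30L))
  # explicit overrides win
  thr <- thresholds_for_model("OOPS", 20, min_size = 5, max_size = 40)
  expect_equal(thr$min_size, 5L)
  expect_equal(thr$max_size, 40L)
})

test_that("the projection position maximizes subset relative entropy", {
  B0 <- uniform_background()
  # one unanimous column among uniform ones
  set.seed(13)
  strs <- vapply(1:40, function(i) {
    v <- sample(BASES, 6, replace = TRUE)
    v[4] <- "G"
    paste(v, collapse = "")
  }, character(1))
  X <- lmers_of(strs)
  idx <- seq_len(nrow(X$mat))
  expect_equal(select_projection_position(X, idx, integer(0), B0), 4L)
  # excluded when already fixed on the path
  expect_true(select_projection_position(X, idx, 4L, B0) != 4L)

  # brute-force recomputation agrees on random subsets
  for (rep in 1:5) {
    strs2 <- vapply(1:30, function(i) rand_dna(5), character(1))
    X2 <- lmers_of(strs2)
    H <- position_entropy(build_pfm(X2$mat, eps = 1), B0)
    expect_equal(select_projection_position(X2, seq_len(30), integer(0), B0),
                 which.max(H))
  }

  # all columns identical distributions: tie resolves to position 1
  X3 <- lmers_of(rep("ACGT", 8))
  expect_equal(select_projection_position(X3, 1:8, integer(0), B0), 1L)
})

test_that("splitting partitions a subset by base in alphabet order", {
  X <- lmers_of(c("ACG", "AAG", "CCG"))
  ch <- split_at(X, 1:3, 1L)
  expect_equal(ch$A, c(1L, 2L))
  expect_equal(ch$C, 3L)
  expect_equal(length(ch$G) + length(ch$T), 0L)
  expect_equal(sort(unname(unlist(ch))), 1:3)

  set.seed(2)
  X2 <- lmers_of(replicate(25, rand_dna(4)))
  ch2 <- split_at(X2, 1:25, 3L)
  expect_equal(sum(lengths(ch2)), 25L)
  expect_equal(sort(unname(unlist(ch2))), 1:25)
})

test_that("projection emits bounded candidates deterministically", {
  B0 <- uniform_background()
  # already inside the window: emitted untouched
  X1 <- lmers_of(rep("ACGTACGT", 10))
  pr1 <- project(X1, B0, min_size = 5, max_size = 15)
  expect_length(pr1$candidates, 1L)
  expect_equal(sort(pr1$candidates[[1]]$idx), 1:10)

  # the full l=3 string space splits once into four subsets of 16
  all3 <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  X2 <- lmers_of(all3)
  pr2 <- project(X2, B0, min_size = 1, max_size = 16)
  expect_length(pr2$candidates, 4L)
  expect_true(all(vapply(pr2$candidates, function(cc) length(cc$idx),
                         integer(1)) == 16L))

  # emitted candidates respect the window; count bounded by n / min_size
  set.seed(31)
  S <- seq_set(replicate(12, rand_dna(120)))
  X3 <- extract_lmers(S, 7)
  pr3 <- project(X3, B0, min_size = 9, max_size = 12)
  sizes <- vapply(pr3$candidates, function(cc) length(cc$idx), integer(1))
  ov <- vapply(pr3$candidates, function(cc) cc$overflow, logical(1))
  expect_true(all(sizes[!ov] >= 9 & sizes[!ov] <= 12))
  expect_lte(length(pr3$candidates), nrow(X3$mat) / 9)

  # disjointness: no l-mer in two candidates
  allidx <- unlist(lapply(pr3$candidates, `[[`, "idx"))
  expect_equal(anyDuplicated(allidx), 0L)
})

test_that("a repeat-saturated dataset collapses to one degenerate candidate", {
  B0 <- uniform_background()
  S <- seq_set(rep(strrep("A", 40), 10))
  X <- extract_lmers(S, 8)
  expect_warning(pr <- project(X, B0, min_size = 8, max_size = 10),
                 "degenerate")
  expect_length(pr$candidates, 1L)
  expect_true(pr$candidates[[1]]$overflow)
  expect_equal(length(pr$candidates[[1]]$idx), nrow(X$mat))
})
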