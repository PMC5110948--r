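test_that("hamming distance counts mismatches symmetrically", {
  expect_equal(hamming("ACGT", "ACGT"), 0L)
  expect_equal(hamming("AAAA", "TTTT"), 4L)
  set.seed(4)
  for (rep in 1:10) {
    a <- rand_dna(9)
    b <- rand_dna(9)
    expect_equal(hamming(a, b), hamming(b, a))
  }
  expect_error(hamming("AC", "ACG"), "equal")
})

test_that("pairwise pruning enforces the 2d bound and keeps coherent cores", {
  mat <- mat_of(c(rep("ACGT", 5), "TTTT"))
  pr <- prune_subset(mat, d = 1, method = "pairwise")
  expect_equal(pr$keep, c(rep(TRUE, 5), FALSE))

  # d = l: vacuous bound, nothing removed
  pr2 <- prune_subset(mat, d = 4, method = "pairwise")
  expect_true(all(pr2$keep))

  # post-condition: max pairwise distance <= 2d on random inputs
  set.seed(19)
  for (rep in 1:8) {
    m <- mat_of(replicate(10, rand_dna(6)))
    for (d in 0:2) {
      kept <- m[prune_subset(m, d, method = "pairwise")$keep, , drop = FALSE]
      if (nrow(kept) >= 2) {
        pd <- max(eppmotif:::.pairwise_hamming(kept))
        expect_lte(pd, 2 * d)
      }
    }
  }
})

test_that("consensus pruning leaves every member within 2d of the consensus", {
  set.seed(23)
  core <- rep("ACGTACGT", 6)
  noise <- replicate(4, rand_dna(8))
  mat <- mat_of(c(core, noise))
  pr <- prune_subset(mat, d = 1, method = "consensus")
  kept <- mat[pr$keep, , drop = FALSE]
  cons <- consensus_of(kept, as_string = FALSE)
  expect_true(all(rowSums(kept != matrix(cons, nrow(kept), 8,
                                         byrow = TRUE)) <= 2))
  expect_true(all(pr$keep[1:6]))            # the coherent core survives
})

test_that("recruitment adds matching instances and records a monotone trace", {
  # planted fixture with exact instances: the missing ones get recruited
  ds <- make_planted_ld_fixture(t = 8, n = 60, l = 6, d = 0, seed = 101)
  X <- extract_lmers(ds$S, 6)
  B <- estimate_background(ds$S)
  truth_rows <- vapply(seq_len(8), function(i)
    which(X$seq_index == i & X$start == ds$truth$start[i]), integer(1))
  rec <- recruit_instances(truth_rows[1:4], X, d = 0, B)
  expect_setequal(rec$idx, truth_rows)       # all 8 instances found
  add <- which(rec$trace_kind == "addition")
  expect_true(all(rec$ic_trace[add] > rec$ic_trace[add - 1L]))

  # idempotence: starting from the full set changes nothing
  rec2 <- recruit_instances(truth_rows, X, d = 0, B)
  expect_setequal(rec2$idx, truth_rows)

  # beyond the 2d bound nothing is added regardless of information
  mat_far <- X$mat[setdiff(seq_len(nrow(X$mat)), truth_rows), , drop = FALSE]
  cons <- consensus_of(X$mat[truth_rows, , drop = FALSE], as_string = FALSE)
  far <- which(eppmotif:::hamming_to_all(X$mat, cons) > 0)
  rec3 <- recruit_instances(truth_rows, X, d = 0, B, model = "TCM")
  expect_true(all(!rec3$idx %in% far))
})

test_that("refinement drops degenerate subsets and sorts by information", {
  ds <- generate_dataset(l = 12, conservation = "high", t = 12, n = 150,
                         seed = 77)
  X <- extract_lmers(ds$S, 12)
  B <- estimate_background(ds$S)
  thr <- thresholds_for_model("OOPS", 12)
  pr <- project(X, B, thr$min_size, thr$max_size)
  fl <- filter_candidates(pr$candidates, X, B, keep_top = 10L)
  motifs <- refine_all(fl$qualified, X, d = 2, thr$min_size, B)
  expect_gt(length(motifs), 0L)
  ics <- vapply(motifs, function(m) m$ic, numeric(1))
  expect_true(all(diff(ics) <= 0))          # non-increasing IC
  expect_true(all(vapply(motifs, function(m) m$n_members, integer(1)) >=
                    thr$min_size))
  # OOPS: one site per sequence
  expect_true(all(vapply(motifs, function(m)
    anyDuplicated(m$sites$seq_index) == 0L, logical(1))))
})
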