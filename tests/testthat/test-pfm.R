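test_that("PFM frequencies follow the pseudocount formula and reconstruct counts", {
  F0 <- build_pfm(c("AC", "AC"), eps = 0)
  expect_equal(F0$freqs[1, 1], 1)
  expect_equal(F0$freqs[2, 2], 1)

  F1 <- build_pfm(c("A", "C", "G", "T"), eps = 0)
  expect_equal(as.numeric(F1$freqs), rep(0.25, 4))

  F2 <- build_pfm(c("ACG", "ACT", "ACG"), eps = 1)
  expect_equal(F2$freqs[3, 3], 3 / 7)

  # un-normalizing recovers the integer counts exactly
  set.seed(3)
  mem <- replicate(9, rand_dna(6))
  F3 <- build_pfm(mem, eps = 1)
  rec <- F3$freqs * (F3$n_members + 4 * F3$eps) - F3$eps
  expect_equal(rec, F3$counts, tolerance = 1e-12)
  expect_equal(rowSums(F3$freqs), rep(1, 6), tolerance = 1e-9)

  expect_error(build_pfm(c("AC", "ACG")), "equal length")
})

test_that("position entropy is a nonnegative relative entropy", {
  B0 <- uniform_background()
  F_flat <- build_pfm(c("A", "C", "G", "T"), eps = 0)
  expect_equal(position_entropy(F_flat, B0), 0)
  expect_equal(ic_independent(F_flat, B0), 0)

  F_cons <- build_pfm(rep("A", 500), eps = 1e-6)
  expect_equal(position_entropy(F_cons, B0), log(4), tolerance = 1e-3)

  set.seed(5)
  for (rep in 1:10) {
    F_r <- build_pfm(replicate(7, rand_dna(5)), eps = 0.5)
    expect_true(all(position_entropy(F_r, B0) >= 0))
    expect_equal(ic_independent(F_r, B0), sum(position_entropy(F_r, B0)))
  }
})

test_that("pair table is normalized and matches column products when independent", {
  B0 <- uniform_background()
  mem <- rep(c("GTAC", "GTCA", "GTGG", "GTTT"), 8)
  P <- pair_table(mem, B0)
  expect_gt(P$phi[1, 3, 4], 0.8)          # unanimous GT pair
  for (w in 1:3) {
    expect_equal(sum(P$phi[w, , ]), 1, tolerance = 1e-9)
  }
  expect_equal(sum(P$phi0), 1, tolerance = 1e-9)

  # independent columns: phi close to outer product of marginals
  set.seed(8)
  mem2 <- replicate(2000, paste(sample(BASES, 2, replace = TRUE,
                                       prob = c(0.5, 0.3, 0.1, 0.1)),
                                collapse = ""))
  P2 <- pair_table(mem2, B0, eps = 0.25)
  F2 <- build_pfm(mem2, eps = 1)
  expect_equal(P2$phi[1, , ], outer(F2$freqs[1, ], F2$freqs[2, ]),
               tolerance = 0.05)
})

test_that("dependency-aware IC behaves like an information content", {
  B0 <- uniform_background()
  set.seed(21)
  # background-drawn members carry (almost) no information
  bg <- matrix(sample.int(4L, 1000 * 8, replace = TRUE), ncol = 8)
  expect_lt(abs(ic_dependent(bg, B0)), 0.1)

  # perfectly conserved members approach l * log 4
  cons <- matrix(2L, 400, 5)
  expect_equal(ic_dependent(cons, B0, eps = 0.01), 5 * log(4),
               tolerance = 0.1)

  # independent columns: pair correction vanishes, IC matches the
  # independent-column IC computed from the same PFM
  probs <- matrix(c(0.7, 0.1, 0.1, 0.1,
                    0.1, 0.6, 0.2, 0.1,
                    0.25, 0.25, 0.25, 0.25,
                    0.1, 0.1, 0.1, 0.7), 4, 4, byrow = TRUE)
  mem <- vapply(1:3000, function(i)
    paste(BASES[vapply(1:4, function(w)
      sample.int(4L, 1L, prob = probs[w, ]), integer(1))], collapse = ""),
    character(1))
  icd <- ic_dependent(mem, B0, eps = 1)
  ici <- ic_independent(build_pfm(mem, eps = 1), B0)
  expect_equal(icd, ici, tolerance = 0.05)

  # conservation ordering: sharper member sets carry more information
  sharp <- matrix(1L, 50, 6)
  set.seed(9)
  fuzzy <- sharp
  flip <- cbind(sample(1:50, 30, TRUE), sample(1:6, 30, TRUE))
  fuzzy[flip] <- sample(2:4, 30, TRUE)
  expect_gt(ic_dependent(sharp, B0), ic_dependent(fuzzy, B0))
})

test_that("majority consensus resolves ties in alphabet order", {
  expect_equal(consensus_of(c("ACG", "ACG")), "ACG")
  expect_equal(consensus_of(c("AAG", "ACG", "ACG")), "ACG")
  expect_equal(consensus_of(c("AC", "GT")), "AC")
})
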