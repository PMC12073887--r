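test_that("position sets are distinct, in range, and seeded", {
  # only one possible set: returned once
  s <- sample_position_sets(5, 5, count = 3)
  expect_identical(s, matrix(1:5, 1))
  # plenty of room: all distinct
  s2 <- sample_position_sets(100, 2, count = 3000, seed = 1)
  expect_identical(nrow(s2), 3000L)
  expect_identical(anyDuplicated(paste(s2[, 1], s2[, 2])), 0L)
  expect_true(all(s2[, 1] < s2[, 2]))
  # reproducibility
  expect_identical(s2, sample_position_sets(100, 2, count = 3000, seed = 1))
  expect_error(sample_position_sets(5, 6, 10), "exceeds")
})

test_that("word frequencies match hand counts", {
  msa <- msa_from_strings(c("ARN", "ARN", "ARN"))
  wf <- word_frequencies(msa, c(1, 3))
  expect_identical(nrow(wf), 1L)
  expect_equal(wf$freq, 1.0)
  expect_identical(wf$word, "AN")
  # {AB:2, AC:1, DB:1} toy at a column pair
  toy <- msa_from_strings(c("AN", "AN", "AC", "DN"))
  wf2 <- word_frequencies(toy, c(1, 2))
  expect_equal(wf2$freq[wf2$word == "AN"], 0.5)
  expect_equal(wf2$freq[wf2$word == "AC"], 0.25)
  expect_equal(wf2$freq[wf2$word == "DN"], 0.25)
  # absent word scores zero
  wf3 <- word_frequencies(toy, c(1, 2), words = rbind(c(2L, 2L)))
  expect_equal(wf3$freq, 0)
  expect_error(word_frequencies(toy, c(1, 9)), "range")
})

test_that("r20 of an MSA against itself is 1 at every order", {
  msa <- random_msa(200, 12, q = 6, seed = 3)
  res <- r20(msa, msa, orders = 2:4, n_sets = 50, seed = 4)
  expect_true(all(abs(res$summary$mean_r - 1) < 1e-12))
  expect_true(all(res$summary$n_used > 0))
})

test_that("r20 is invariant to row order and checks its preconditions", {
  truth <- random_potts(10, q = 5, density = 0.4, scale = 0.8, seed = 11)
  ref <- generate_iid_msa(truth, 800, seed = 12, nsweeps = 60)
  ev <- generate_iid_msa(truth, 800, seed = 13, nsweeps = 60)
  ps <- position_sets(10, orders = 2:3, n_sets = 40, seed = 14)
  base <- r20(ref, ev, position_sets = ps)
  set.seed(15)
  shuf <- `[.encoded_msa`(ev, sample(800))
  again <- r20(ref, shuf, position_sets = ps)
  expect_equal(again$summary$mean_r, base$summary$mean_r, tolerance = 1e-12)
  expect_error(r20(ref, random_msa(10, 9, q = 5)), "share L")
})

test_that("null r20 of identical MSAs is 1 and the evaluation role is honored", {
  msa <- random_msa(300, 10, q = 4, seed = 21)
  res <- null_r20(msa, msa, orders = 2:3, n_sets = 30, seed = 22)
  expect_true(all(abs(res$summary$mean_r - 1) < 1e-12))
  # null_r20(a, b) == r20(b, a): words always from the reference
  a <- random_msa(300, 10, q = 4, seed = 23)
  b <- random_msa(300, 10, q = 4, seed = 24)
  ps <- position_sets(10, orders = 2:3, n_sets = 40, seed = 25)
  expect_equal(null_r20(a, b, position_sets = ps)$summary$mean_r,
               r20(b, a, position_sets = ps)$summary$mean_r)
})

test_that("connected correlations obey the printed pairwise formula", {
  # f_AB = 0.5, f_A = f_B = 0.5 -> C = 0.25
  f <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  expect_equal(connected_correlation(f, c(1L, 1L)), 0.25)
  # order-1 base case returns the site frequency
  expect_equal(connected_correlation(c(0.3, 0.7), 2L), 0.7)
  expect_error(connected_correlation(f, c(1L, 1L, 1L)), "rank")
})

test_that("connected correlations vanish under product distributions", {
  set.seed(31)
  margs <- lapply(c(3, 2, 4, 2), function(k) {
    p <- runif(k); p / sum(p)
  })
  for (n in 2:4) {
    f <- Reduce(function(a, b) outer(a, b), margs[seq_len(n)])
    dims <- dim(f)
    for (rep in 1:5) {
      w <- vapply(dims, function(d) sample.int(d, 1L), integer(1))
      expect_lt(abs(connected_correlation(f, w)), 1e-12)
    }
  }
})

test_that("the cumulant recursion equals the brute-force partition sum", {
  set.seed(41)
  for (n in 2:4) {
    f <- array(runif(2^n), dim = rep(2, n))
    f <- f / sum(f)
    for (rep in 1:4) {
      w <- sample(1:2, n, replace = TRUE)
      expect_equal(connected_correlation(f, w), brute_cc(f, w),
                   tolerance = 1e-12)
    }
  }
})

test_that("empirical cc path agrees with the exact path on plug-in marginals", {
  msa <- random_msa(150, 6, q = 3, seed = 51)
  cols <- c(2L, 4L, 5L)
  # empirical joint distribution as an array
  f <- array(0, dim = rep(3, 3))
  for (r in seq_len(150)) {
    w <- msa$codes[r, cols]
    f[w[1], w[2], w[3]] <- f[w[1], w[2], w[3]] + 1 / 150
  }
  words <- rbind(c(1L, 1L, 1L), c(2L, 3L, 1L))
  got <- gpsmeval:::.empirical_cc(msa$codes, cols, words, 3L)
  expect_equal(got[1], connected_correlation(f, words[1, ]),
               tolerance = 1e-12)
  expect_equal(got[2], connected_correlation(f, words[2, ]),
               tolerance = 1e-12)
})

test_that("cc-r20 is 1 on self and near the permutation null for independent data", {
  truth <- random_potts(10, q = 4, density = 0.5, scale = 1, seed = 61)
  ref <- generate_iid_msa(truth, 1500, seed = 62, nsweeps = 60)
  ps <- position_sets(10, orders = 2:3, n_sets = 60, seed = 63)
  self <- cc_r20(ref, ref, position_sets = ps)
  expect_true(all(abs(self$summary$mean_r - 1) < 1e-12))
})

test_that("degenerate reference sets are skipped, not averaged as NaN", {
  # constant MSA: every reference frequency vector has zero variance
  msa <- msa_from_strings(c("AAAA", "AAAA", "AAAA"))
  res <- r20(msa, msa, orders = 2, n_sets = 4, seed = 71)
  expect_identical(res$summary$n_used, 0L)
  expect_identical(res$summary$n_skipped, res$summary$n_sets)
  expect_true(is.na(res$summary$mean_r))
})
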