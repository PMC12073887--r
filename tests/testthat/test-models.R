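test_that("marginal estimation matches hand counts and the blend limits", {
  # single sequence, zero pseudocount: delta marginals
  one <- msa_from_strings("AA")
  m <- estimate_marginals(one)
  expect_equal(m$f1[1L, ], c(1, rep(0, 20)))
  # toy counts {AB:2, AC:1, DB:1} at a column pair
  toy <- msa_from_strings(c("AN", "AN", "AC", "DN"))
  mt <- estimate_marginals(toy)
  a <- 1L; n <- 12L; cc <- 2L; d <- 3L
  expect_equal(mt$f2[a, n, 1L], 0.5)
  expect_equal(mt$f2[a, cc, 1L], 0.25)
  expect_equal(mt$f2[d, n, 1L], 0.25)
  # huge pseudocount drives everything to uniform
  mu <- estimate_marginals(toy, pseudocount_scale = 1e9)
  expect_equal(max(abs(mu$f1 - 1 / 21)), 0, tolerance = 1e-6)
  expect_error(estimate_marginals(toy, -1), "nonnegative")
})

test_that("pseudocounted marginals keep their normalization invariants", {
  msa <- random_msa(40, 8, q = 6, seed = 5)
  for (scale in c(0, 1 / 40, 0.5)) {
    m <- estimate_marginals(msa, scale)
    expect_equal(rowSums(m$f1), rep(1, 8), tolerance = 1e-12)
    pairs <- combn(8, 2)
    for (p in seq_len(ncol(pairs))) {
      blk <- m$f2[, , p]
      expect_equal(sum(blk), 1, tolerance = 1e-12)
      expect_equal(rowSums(blk), m$f1[pairs[1L, p], ], tolerance = 1e-12)
      expect_equal(colSums(blk), m$f1[pairs[2L, p], ], tolerance = 1e-12)
    }
    expect_true(all(m$f2 >= 0))
  }
})

test_that("Potts energies agree with a brute-force double loop", {
  # the printed two-state example
  J <- array(c(1, 0, 0, 1), c(2, 2, 1))
  m <- potts_model(J, alphabet = aa_alphabet(2))
  expect_equal(potts_energy(m, c(1L, 1L)), 1)
  expect_equal(potts_energy(m, c(1L, 2L)), 0)
  # zero couplings: zero energy everywhere
  m0 <- random_potts(6, q = 4, density = 0, seed = 1)
  msa <- random_msa(10, 6, q = 4, seed = 2)
  expect_equal(potts_energy(m0, msa), rep(0, 10))
  # random couplings + fields vs the oracle
  set.seed(3)
  mr <- potts_model(array(rnorm(3 * 3 * 3), c(3, 3, 3)),
                    h = matrix(rnorm(9), 3, 3),
                    alphabet = aa_alphabet(3))
  msa3 <- random_msa(20, 3, q = 3, seed = 4)
  oracle <- apply(msa3$codes, 1L, function(s) brute_energy(mr, s))
  expect_equal(potts_energy(mr, msa3), oracle, tolerance = 1e-12)
})

test_that("gauge shifts leave probabilities invariant (enumeration)", {
  set.seed(11)
  m <- potts_model(array(rnorm(27), c(3, 3, 3)), alphabet = aa_alphabet(3))
  d <- exact_distribution(m)
  # adding a constant to a whole block shifts all energies equally
  m2 <- m
  m2$J[, , 2L] <- m2$J[, , 2L] + 1.7
  e1 <- potts_energy(m, enumerate_states(3, 3))
  e2 <- potts_energy(m2, enumerate_states(3, 3))
  expect_equal(e2 - e1, rep(1.7, 27), tolerance = 1e-12)
  expect_equal(exact_distribution(m2)$p, d$p, tolerance = 1e-12)
  # zero-sum gauge: probabilities identical, row/col sums vanish
  mz <- zero_sum_gauge(m)
  expect_equal(exact_distribution(mz)$p, d$p, tolerance = 1e-12)
  for (p in 1:3) {
    expect_equal(rowSums(mz$J[, , p]), rep(0, 3), tolerance = 1e-10)
    expect_equal(colSums(mz$J[, , p]), rep(0, 3), tolerance = 1e-10)
  }
  # already zero-sum couplings with no fields stay unchanged
  rz <- random_potts(4, q = 3, density = 1, scale = 1, seed = 12)
  rz2 <- zero_sum_gauge(rz)
  expect_equal(rz2$J, rz$J, tolerance = 1e-12)
  expect_null(rz2$h)
  # constant couplings collapse to zero
  mc <- potts_model(array(2, c(3, 3, 3)), alphabet = aa_alphabet(3))
  expect_equal(max(abs(zero_sum_gauge(mc)$J)), 0)
})

test_that("exact enumeration matches the brute-force distribution", {
  set.seed(21)
  m <- potts_model(array(rnorm(2 * 2 * 6, sd = 0.8), c(2, 2, 6)),
                   alphabet = aa_alphabet(2))
  b <- brute_distribution(m)
  d <- exact_distribution(m)
  # align states: brute grid varies column 1 fastest too
  expect_equal(d$states, b$states)
  expect_equal(d$p, b$p, tolerance = 1e-12)
  em <- exact_marginals(m)
  # single-site marginal from brute distribution
  f1_brute <- vapply(1:4, function(i) {
    vapply(1:2, function(a) sum(b$p[b$states[, i] == a]), numeric(1))
  }, numeric(2))
  expect_equal(em$f1, t(f1_brute), tolerance = 1e-12)
})

test_that("MCMC sampling reproduces exact marginals and is reproducible", {
  # flat landscape: uniform columns
  m0 <- random_potts(4, q = 5, density = 0, seed = 1)
  s0 <- sample_potts(m0, 4000, nsweeps = 20, seed = 2)
  f1 <- estimate_marginals(s0)$f1
  se <- sqrt(0.2 * 0.8 / 4000)
  expect_lt(max(abs(f1 - 0.2)), 4 * se)
  # coupled model vs enumeration at L=3, q=2
  mc <- random_potts(3, q = 2, density = 1, scale = 1, seed = 3)
  em <- exact_marginals(mc)
  sm <- estimate_marginals(sample_potts(mc, 20000, nsweeps = 60, seed = 4))
  z <- abs(sm$f2 - em$f2) / sqrt(pmax(em$f2 * (1 - em$f2), 1e-9) / 20000)
  expect_lt(max(z), 4.5)
  expect_lt(mean(z > 3), 0.01 + 1e-9)
  # seeding contract
  a <- sample_potts(mc, 50, nsweeps = 10, seed = 9)
  b <- sample_potts(mc, 50, nsweeps = 10, seed = 9)
  cc <- sample_potts(mc, 50, nsweeps = 10, seed = 10)
  expect_identical(a$codes, b$codes)
  expect_false(identical(a$codes, cc$codes))
  expect_error(sample_potts(mc, 0), "n_seq")
})

test_that("marginal matching recovers flat couplings on independent data", {
  # data from an independent model: fitted zero-sum couplings ~ 0,
  # compared against a column-permutation refit (same marginal noise,
  # couplings guaranteed spurious)
  set.seed(31)
  msa <- random_msa(2000, 5, q = 4, seed = 31)
  fit <- fit_potts(msa, method = "enumerate")
  perm <- msa
  for (i in 1:5) perm$codes[, i] <- sample(perm$codes[, i])
  fit_perm <- fit_potts(perm, method = "enumerate")
  expect_lt(max(abs(coef(fit))), 3 * max(abs(coef(fit_perm))))
  expect_lt(max(abs(coef(fit))), 0.5)
})

test_that("the fitted model reproduces training marginals (fixed point)", {
  truth <- random_potts(5, q = 4, density = 0.5, scale = 0.8, seed = 41)
  msa <- generate_iid_msa(truth, 5000, seed = 42, nsweeps = 50)
  fit <- fit_potts(msa, method = "enumerate")
  tm <- estimate_marginals(msa, 1 / 5000)
  em <- exact_marginals(fit)
  expect_lt(max(abs(em$f2 - tm$f2)), 1e-4)
  # recovery: fitted couplings correlate strongly with the truth
  expect_gt(cor(as.vector(coef(fit)), as.vector(coef(truth))), 0.9)
  # refitting the model on its own exact marginals is a fixed point
  marg <- exact_marginals(fit)
  marg$f2 <- (1 - 1e-9) * marg$f2 + 1e-9 / 16   # keep strictly positive
  marg$f1 <- (1 - 1e-9) * marg$f1 + 1e-9 / 4
  refit <- fit_potts(marg, method = "enumerate")
  expect_gt(cor(as.vector(coef(refit)), as.vector(coef(fit))), 0.99)
})

test_that("fit_potts validates inputs and reports non-convergence", {
  msa <- random_msa(50, 4, q = 4, seed = 51)
  expect_error(fit_potts(msa, pseudocount_scale = 0), "zeros")
  expect_error(fit_potts(msa, maxit = 1L, tol = 1e-12,
                         method = "enumerate"),
               "did not converge")
})

test_that("independent model fits, samples, and stays uncorrelated", {
  # degenerate training data reproduces itself
  const <- msa_from_strings(c("ARN", "ARN", "ARN"))
  ind <- fit_independent(const)
  s <- simulate(ind, nsim = 10, seed = 1)
  expect_true(all(s$codes[, 1L] == 1L))
  expect_identical(nrow(s$codes), 10L)
  # frequencies match within multinomial bounds
  truth <- random_potts(6, q = 6, density = 0.5, scale = 0.7, seed = 2)
  train <- generate_iid_msa(truth, 4000, seed = 3, nsweeps = 60)
  ind2 <- fit_independent(train)
  s2 <- sample_independent(ind2, 8000, seed = 4)
  f1 <- estimate_marginals(s2)$f1
  se <- sqrt(pmax(ind2$f1 * (1 - ind2$f1), 1e-9) / 8000)
  expect_lt(max(abs(f1 - ind2$f1) / pmax(se, 1e-6)), 5)
  # connected pair correlations vanish within the resampling band
  cmax <- mean(abs(pair_covariation(s2)))
  band <- vapply(1:6, function(k) {
    mean(abs(pair_covariation(sample_independent(ind2, 8000,
                                                 seed = 10 + k))))
  }, numeric(1))
  expect_lt(cmax, mean(band) + 4 * sd(band) + 1e-4)
})
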