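test_that("pairwise identity matches the definition, gap as ordinary state", {
  msa <- msa_from_strings(c("ARN-K", "ARNQK"))
  idm <- pairwise_identity(msa)
  expect_equal(idm[1L, 2L], 0.8)         # gap vs Q is a mismatch
  expect_equal(diag(idm), c(1, 1))
  a <- msa$codes[1L, ]
  expect_equal(seq_identity(a, a), 1.0)
  expect_error(seq_identity(a, a[-1L]), "lengths")
  # gap-exclude convention drops gapped columns from the denominator
  expect_equal(seq_identity(msa$codes[1L, ], msa$codes[2L, ],
                            gaps = "exclude"), 1.0)
})

test_that("identity of random sequences concentrates at 1/q", {
  msa <- random_msa(2, 1000, q = 21L, seed = 3)
  obs <- pairwise_identity(msa)[1L, 2L]
  p <- 1 / 21
  se <- sqrt(p * (1 - p) / 1000)
  expect_lt(abs(obs - p), 3 * se)
})

test_that("identity filtering enforces its postcondition", {
  # 10 identical sequences collapse to one survivor
  msa <- encoded_msa(matrix(rep(1:5, each = 10), 10, 5))
  flt <- identity_filter(msa, 0.5, seed = 1)
  expect_length(flt$keep, 1L)
  # an MSA already below threshold is untouched, order preserved
  msa2 <- random_msa(20, 40, seed = 11)
  flt2 <- identity_filter(msa2, 0.5, seed = 1)
  expect_identical(flt2$keep, 1:20)
  expect_identical(flt2$msa$codes, msa2$codes)
  expect_error(identity_filter(msa2, 1.5), "threshold")
})

test_that("every RNG branch of the 3-chain instance satisfies the bound", {
  # A-B and B-C identity 0.6, A-C identity 0.4, threshold 0.5; whatever
  # the seeded drop choices, no surviving pair may exceed 0.5
  a <- rep(1L, 10L)
  b <- c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L)
  cc <- c(3L, 3L, 1L, 1L, 1L, 1L, 2L, 2L, 4L, 4L)
  msa <- encoded_msa(rbind(a, b, cc), alphabet = aa_alphabet(8))
  idm <- pairwise_identity(msa)
  expect_equal(idm[1, 2], 0.6)
  expect_equal(idm[2, 3], 0.6)
  expect_equal(idm[1, 3], 0.4)
  survivor_sets <- character(0)
  for (seed in 1:40) {
    flt <- identity_filter(msa, 0.5, seed = seed)
    sub <- idm[flt$keep, flt$keep, drop = FALSE]
    expect_lte(max(sub[upper.tri(sub)], -Inf), 0.5)
    survivor_sets <- c(survivor_sets, paste(flt$keep, collapse = ","))
  }
  # both branches (drop B -> keep {A,C}; drop A/C then B survives with the
  # other) actually occur across seeds
  expect_gt(length(unique(survivor_sets)), 1L)
})

test_that("filtering is idempotent given identical survivors", {
  msa <- generate_phylo_msa(random_potts(20, q = 8, density = 0, seed = 1),
                            n_clusters = 8, cluster_size = 5,
                            divergence_sweeps = 0.1, seed = 5)$msa
  f1 <- identity_filter(msa, 0.5, seed = 9)
  f2 <- identity_filter(f1$msa, 0.5, seed = 10)
  expect_identical(f2$keep, seq_along(f1$keep))
})

test_that("phylo split partitions survivors and groups relatives", {
  # all mutually dissimilar: plain disjoint partition of everything
  msa <- random_msa(21, 40, seed = 21)
  sp <- phylo_split(msa, 0.5, seed = 2)
  expect_length(intersect(sp$training_idx, sp$reference_idx), 0L)
  expect_setequal(c(sp$training_idx, sp$reference_idx), 1:21)
  # odd survivor goes to training
  expect_length(sp$train_survivors, 11L)
  expect_length(sp$ref_survivors, 10L)
  expect_identical(sp$nearest[sp$train_survivors], sp$train_survivors)

  # one survivor plus near-duplicates: the whole cluster lands together
  base <- random_msa(2, 40, seed = 22)$codes
  dup <- base[c(1L, rep(2L, 6L)), ]
  dup[3:7, 1L] <- ((dup[3:7, 1L]) %% 21L) + 1L   # tiny perturbations
  msa2 <- encoded_msa(dup)
  sp2 <- phylo_split(msa2, 0.5, seed = 3)
  halves <- as.character(sp2$assignment[2:7])
  expect_length(unique(halves), 1L)

  expect_error(phylo_split(msa, 0.5, train_size = 15, ref_size = 15,
                           seed = 1), "exceed")
})

test_that("50% filtering pulls clustered covariation back to the iid level", {
  land <- random_potts(25, q = 8, density = 0, seed = 31)   # flat landscape
  clustered <- generate_phylo_msa(land, n_clusters = 30, cluster_size = 10,
                                  divergence_sweeps = 0.08, seed = 32)$msa
  iid_ref <- vapply(1:8, function(k) {
    mean(abs(pair_covariation(
      generate_iid_msa(land, 300, seed = 100 + k, nsweeps = 50))))
  }, numeric(1))
  band_hi <- max(iid_ref) + 3 * sd(iid_ref)
  unfiltered <- mean(abs(pair_covariation(clustered)))
  expect_gt(unfiltered, band_hi)
  flt <- identity_filter(clustered, 0.5, seed = 33)
  filtered <- mean(abs(pair_covariation(flt$msa)))
  # compare against the iid band at the matching depth
  iid_match <- vapply(1:8, function(k) {
    mean(abs(pair_covariation(
      generate_iid_msa(land, length(flt$keep), seed = 200 + k,
                       nsweeps = 50))))
  }, numeric(1))
  expect_lt(filtered, max(iid_match) + 3 * sd(iid_match))
})
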