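# Synthetic-data generators: random coupling landscapes, i.i.d. Potts
# samples, and phylogenetically clustered MSAs built on a star tree so
# that "evolution" respects the fitness landscape (leaf divergence is
# fitness-weighted MCMC from a shared founder, not random substitution).

#' Random sparse Potts landscape
#'
#' A fraction `density` of column pairs receives a coupling block of
#' i.i.d. Gaussian entries with standard deviation `scale`; the rest are
#' zero. Coupling blocks are returned in the zero-sum gauge, so the
#' landscape is directly comparable to fitted couplings. Optional
#' Gaussian site fields (`field_scale > 0`) skew the single-site
#' frequencies, mimicking the strongly non-uniform residue usage of
#' natural protein families; landscapes distilled from natural
#' alignments are field-rich, and evaluation statistics behave very
#' differently on them than on site-symmetric landscapes.
#'
#' @param L Number of columns (`>= 2`).
#' @param q Number of states including the gap.
#' @param density Fraction of pairs with nonzero couplings, in `[0, 1]`.
#' @param scale Standard deviation of nonzero coupling entries (`>= 0`).
#' @param field_scale Standard deviation of site fields; 0 (default)
#'   omits fields.
#' @param seed Integer seed; identical seeds give identical landscapes.
#' @return A `potts` model (zero-sum gauge).
#' @export
random_potts <- function(L, q = 21L, density = 0.1, scale = 0.5,
                         field_scale = 0, seed = NULL) {
  L <- .check_count(L, "L", min = 2L)
  q <- .check_count(q, "q", min = 2L)
  if (density < 0 || density > 1) stop("`density` must lie in [0, 1]")
  if (scale < 0 || field_scale < 0) stop("scales must be nonnegative")
  npair <- (L * (L - 1L)) %/% 2L
  n_active <- round(density * npair)
  .with_seed(seed, {
    J <- array(0, dim = c(q, q, npair))
    if (n_active > 0L && scale > 0) {
      active <- sample.int(npair, n_active)
      for (p in active) {
        B <- matrix(rnorm(q * q, sd = scale), q, q)
        # project onto the zero-sum gauge; discarded parts are pure
        # single-site structure, which belongs to the fields
        B <- B - outer(rowMeans(B), rep(1, q)) -
          outer(rep(1, q), colMeans(B)) + mean(B)
        J[, , p] <- B
      }
    }
    h <- if (field_scale > 0) {
      hh <- matrix(rnorm(L * q, sd = field_scale), L, q)
      hh - rowMeans(hh)
    } else NULL
    potts_model(J, h = h, alphabet = aa_alphabet(q), gauge = "zero-sum")
  })
}

#' Generate an i.i.d. MSA from a Potts landscape
#'
#' Thin wrapper over [sample_potts()]: one independent, long-burn-in
#' Metropolis chain per sequence, so rows are (approximately) independent
#' draws from `P(S)`.
#'
#' @param model A `potts` model.
#' @param n_seq Number of sequences.
#' @param seed Integer seed.
#' @param nsweeps Sweeps per chain; `NULL` (default) uses the adaptive
#'   equilibration check.
#' @param ... Passed to [sample_potts()].
#' @return An [encoded_msa].
#' @export
generate_iid_msa <- function(model, n_seq, seed = NULL, nsweeps = NULL,
                             ...) {
  sample_potts(model, n_seq = n_seq, nsweeps = nsweeps, seed = seed, ...)
}

#' Generate a phylogenetically clustered MSA
#'
#' Emulates an alignment contaminated by clusters of recently diverged
#' sequences. For each cluster a founder is equilibrated under `P(S)`
#' (long MCMC); `cluster_size` leaves are then produced by running only
#' `divergence_sweeps` further Metropolis sweeps from the founder, so
#' small values give tight clusters of near-duplicates and large values
#' let leaves mix back to independent draws. Rows are shuffled; the
#' cluster of origin is returned for diagnostics. Such clusters inflate
#' apparent pairwise covariation even on a zero-coupling landscape —
#' excess counts of ancestral patterns, not biophysics — which identity
#' filtering is designed to remove.
#'
#' @param model A `potts` model (the fitness landscape).
#' @param n_clusters Number of clusters (founders).
#' @param cluster_size Leaves per founder.
#' @param divergence_sweeps MCMC sweeps from founder to each leaf; 0
#'   yields identical copies. May be fractional: divergence runs as
#'   `round(divergence_sweeps * L)` random-scan single-site updates, so
#'   values well below 1 give tight clusters of near-duplicates even on
#'   fast-mixing (weak-coupling) landscapes.
#' @param founder_sweeps Sweeps used to equilibrate founders (`NULL`:
#'   adaptive check).
#' @param seed Integer seed.
#' @return List: `msa` (an [encoded_msa]), `cluster` (integer label per
#'   row).
#' @export
generate_phylo_msa <- function(model, n_clusters, cluster_size,
                               divergence_sweeps, founder_sweeps = NULL,
                               seed = NULL) {
  stopifnot(inherits(model, "potts"))
  n_clusters <- .check_count(n_clusters, "n_clusters")
  cluster_size <- .check_count(cluster_size, "cluster_size")
  if (!is.numeric(divergence_sweeps) || divergence_sweeps < 0) {
    stop("`divergence_sweeps` must be nonnegative")
  }
  nsteps <- as.integer(round(divergence_sweeps * model$L))
  .with_seed(seed, {
    founders <- sample_potts(model, n_seq = n_clusters,
                             nsweeps = founder_sweeps)
    leaves <- founders$codes[rep(seq_len(n_clusters), each = cluster_size),
                             , drop = FALSE]
    labels <- rep(seq_len(n_clusters), each = cluster_size)
    if (nsteps > 0L) {
      leaves <- cpp_sample_potts_steps(leaves, model$J, model$h, model$q,
                                       nsteps)
    }
    perm <- sample.int(nrow(leaves))
    list(msa = encoded_msa(leaves[perm, , drop = FALSE],
                           alphabet = model$alphabet),
         cluster = labels[perm])
  })
}
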