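# Exact enumeration of the sequence space, used as the ground-truth oracle
# for MCMC and inference whenever q^L is small enough, and as the exact
# gradient back-end of fit_potts().

.enum_guard <- function(q, L, limit = 1e6) {
  n_states <- q^L
  if (n_states > limit) {
    stop(sprintf("q^L = %.3g exceeds the enumeration limit %g", n_states,
                 limit))
  }
  as.integer(n_states)
}

#' Enumerate all sequences of length L over q states
#'
#' @param L,q Sequence length and state count; requires `q^L <= 1e6`.
#' @return `q^L x L` integer matrix of 1-based codes; row order is the
#'   mixed-radix counter with column 1 varying fastest.
#' @export
enumerate_states <- function(L, q) {
  n <- .enum_guard(q, L)
  idx <- 0:(n - 1L)
  codes <- matrix(0L, n, L)
  for (k in seq_len(L)) {
    codes[, k] <- as.integer((idx %/% q^(k - 1L)) %% q) + 1L
  }
  codes
}

#' Exact Boltzmann distribution of a Potts model
#'
#' Enumerates all `q^L` sequences, computes energies, and normalizes
#' `P(S) = exp(-E(S)) / Z`.
#'
#' @param model A `potts` model (see [fit_potts()], [random_potts()],
#'   [potts_model()]).
#' @return List: `states` (code matrix), `p` (probabilities), `logZ`.
#' @export
exact_distribution <- function(model) {
  stopifnot(inherits(model, "potts"))
  states <- enumerate_states(model$L, model$q)
  E <- cpp_energies(states, model$J, model$h, model$q)
  m <- min(E)
  w <- exp(-(E - m))
  Z <- sum(w)
  list(states = states, p = w / Z, logZ = log(Z) - m)
}

#' Exact single-site and bivariate marginals of a Potts model
#'
#' @inheritParams exact_distribution
#' @return A `"marginal_set"` (zero pseudocount) holding the model's exact
#'   `f1` and `f2`.
#' @export
exact_marginals <- function(model) {
  d <- exact_distribution(model)
  L <- model$L; q <- model$q
  f1 <- t(vapply(seq_len(L), function(i) {
    .wtab(d$states[, i], d$p, q)
  }, numeric(q)))
  f2 <- cpp_pair_counts_weighted(d$states, d$p, q)
  structure(list(f1 = f1, f2 = f2, pseudocount_scale = 0,
                 n_source = Inf, L = L, q = q),
            class = "marginal_set")
}

#' Exact joint distribution over a column subset
#'
#' Marginalizes the full Boltzmann distribution onto `columns`, returning
#' an `n`-dimensional `q x ... x q` array — the exact input expected by
#' [connected_correlation()].
#'
#' @inheritParams exact_distribution
#' @param columns Strictly increasing column indices.
#' @return Array of joint probabilities with one dimension per column.
#' @export
exact_joint <- function(model, columns) {
  stopifnot(inherits(model, "potts"))
  columns <- as.integer(columns)
  if (is.unsorted(columns, strictly = TRUE) || any(columns < 1L) ||
      any(columns > model$L)) {
    stop("`columns` must be strictly increasing indices in 1..L")
  }
  d <- exact_distribution(model)
  q <- model$q
  n <- length(columns)
  idx <- rep(1, nrow(d$states))
  for (k in seq_len(n)) {
    idx <- idx + (d$states[, columns[k]] - 1) * q^(k - 1)
  }
  array(.wtab(idx, d$p, q^n), dim = rep(q, n))
}

# weighted tabulate: sum of w within integer bins 1..nbins
.wtab <- function(idx, w, nbins) {
  out <- numeric(nbins)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s
  out
}
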