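# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's computational paths (C++ energy code,
# cumulant recursion) so they can vouch for them.

# Build an encoded MSA from aligned strings.
msa_from_strings <- function(x, alphabet = aa_alphabet()) {
  encode_msa(x, alphabet = alphabet)
}

# Random MSA with given dimensions over q states.
random_msa <- function(n, l, q = 21L, seed = 1L) {
  set.seed(seed)
  encoded_msa(matrix(sample.int(q, n * l, replace = TRUE), n, l),
              alphabet = aa_alphabet(q))
}

# Brute-force Potts energy: direct double loop over ordered pairs.
brute_energy <- function(model, s) {
  L <- model$L
  e <- 0
  p <- 0L
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      p <- p + 1L
      e <- e + model$J[s[i], s[j], p]
    }
  }
  if (!is.null(model$h)) {
    for (i in seq_len(L)) e <- e + model$h[i, s[i]]
  }
  e
}

# Brute-force Boltzmann distribution by looping over all states in R.
brute_distribution <- function(model) {
  L <- model$L; q <- model$q
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(q)), L)))
  e <- apply(grid, 1L, function(s) brute_energy(model, s))
  w <- exp(-(e - min(e)))
  list(states = unname(grid), p = w / sum(w))
}

# All set partitions of a vector (each partition is a list of blocks).
set_partitions <- function(items) {
  if (length(items) == 1L) return(list(list(items)))
  first <- items[1L]
  rest <- set_partitions(items[-1L])
  out <- list()
  for (p in rest) {
    for (k in seq_along(p)) {
      np <- p
      np[[k]] <- c(first, np[[k]])
      out[[length(out) + 1L]] <- np
    }
    out[[length(out) + 1L]] <- c(list(first), p)
  }
  out
}

# Brute-force connected correlation by the explicit partition sum:
# g(A) = f(A) - sum over partitions with >= 2 blocks of prod g(B).
# `f` is an n-dimensional joint frequency array, `word` a code tuple.
brute_cc <- function(f, word) {
  n <- length(word)
  moment <- function(bits) {
    marg <- apply(f, bits, sum)
    marg[matrix(word[bits], nrow = 1L)]
  }
  g <- function(bits) {
    if (length(bits) == 1L) return(moment(bits))
    total <- 0
    for (p in set_partitions(bits)) {
      if (length(p) == 1L) next
      total <- total + prod(vapply(p, g, numeric(1)))
    }
    moment(bits) - total
  }
  g(seq_len(n))
}
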