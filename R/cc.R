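# Connected correlations (Ursell functions / joint cumulants).
#
# For a word w at a position set A, let X_i be the indicator that column i
# carries w_i, and m(B) = E[prod_{i in B} X_i] the joint frequency of the
# sub-word on B. The connected correlation g(A) is the joint cumulant of
# the X_i: the moment decomposes over set partitions as
# m(A) = sum_P prod_{B in P} g(B), so g(A) is m(A) minus everything
# explainable by proper factorizations. At n = 2 this is the familiar
# pairwise covariation C = f_ab - f_a f_b; under a product (independent)
# distribution it vanishes for every order >= 2. Computation uses the
# standard first-element recursion
#   g(A) = m(A) - sum_{C: a1 in C, C proper subset of A} g(C) m(A \ C),
# equivalent to (and much cheaper than) the explicit partition sum.

.cc_env <- new.env(parent = emptyenv())

# recursion plan for word size n: for each subset mask (bitmask over
# positions), the list of (C, A\C) index pairs with a1 in C
.cc_plan <- function(n) {
  key <- as.character(n)
  if (!is.null(.cc_env[[key]])) return(.cc_env[[key]])
  n_masks <- bitwShiftL(1L, n) - 1L
  bits_of <- lapply(seq_len(n_masks), function(mask) {
    which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) > 0L)
  })
  plan <- vector("list", n_masks)
  for (mask in seq_len(n_masks)) {
    bits <- bits_of[[mask]]
    if (length(bits) < 2L) next
    fb <- bitwShiftL(1L, bits[1L] - 1L)
    rest <- mask - fb
    cs <- integer(0)
    s <- rest
    repeat {
      s <- bitwAnd(s - 1L, rest)
      cs <- c(cs, fb + s)
      if (s == 0L) break
    }
    plan[[mask]] <- cbind(C = cs, D = mask - cs)
  }
  out <- list(n_masks = n_masks, bits_of = bits_of, plan = plan,
              popcount = lengths(bits_of))
  .cc_env[[key]] <- out
  out
}

# moments (masks x words) -> cumulants of the full word; `m` has one row
# per nonempty subset mask
.cumulants <- function(m, n) {
  pl <- .cc_plan(n)
  kappa <- m
  for (mask in order(pl$popcount[seq_len(pl$n_masks)])) {
    if (pl$popcount[mask] < 2L) next
    acc <- m[mask, ]
    sub <- pl$plan[[mask]]
    for (r in seq_len(nrow(sub))) {
      acc <- acc - kappa[sub[r, 1L], ] * m[sub[r, 2L], ]
    }
    kappa[mask, ] <- acc
  }
  kappa
}

# frequency of each requested id among `ids`, tolerating duplicate
# requested ids (several words can share a sub-word on a subset)
.freq_of_dup <- function(ids, wanted) {
  uq <- unique(wanted)
  cnt <- tabulate(match(ids, uq), nbins = length(uq))
  cnt[match(wanted, uq)] / length(ids)
}

# empirical connected correlations of k words (rows of `words`) at
# columns `cols` of a code matrix
.empirical_cc <- function(codes, cols, words, q) {
  n <- length(cols)
  k <- nrow(words)
  pl <- .cc_plan(n)
  m <- matrix(0, pl$n_masks, k)
  for (mask in seq_len(pl$n_masks)) {
    bits <- pl$bits_of[[mask]]
    sub_ids <- .word_ids(codes, cols[bits], q)
    wids <- .word_ids(words[, bits, drop = FALSE], seq_along(bits), q)
    m[mask, ] <- .freq_of_dup(sub_ids, wids)
  }
  .cumulants(m, n)[pl$n_masks, ]
}

#' Connected correlation (Ursell function) of a word
#'
#' Computes the joint-cumulant part of a word's frequency under a given
#' joint distribution over a position set: the portion of `f(word)` not
#' explained by any factorization over proper subsets of the positions.
#' At order 2 this is the pairwise covariation `f_ab - f_a f_b`; under a
#' product distribution it is 0 for all orders `>= 2`. The order-1 base
#' case returns the single-site frequency itself.
#'
#' @param f An `n`-dimensional array of joint frequencies over the
#'   position set (exact, e.g. from [exact_joint()], or empirical), or a
#'   numeric vector for `n = 1`.
#' @param word Integer code tuple of length `n`.
#' @return The connected correlation, a single number.
#' @examples
#' # independent columns: cc vanishes
#' f <- outer(c(.7, .3), c(.4, .6))
#' connected_correlation(f, c(1, 1))  # 0
#' @export
connected_correlation <- function(f, word) {
  if (is.null(dim(f))) {
    if (length(word) != 1L) stop("vector `f` implies a single position")
    return(f[word])
  }
  n <- length(dim(f))
  if (length(word) != n) stop("`word` length must match the array rank")
  if (any(word < 1L | word > dim(f))) stop("`word` outside array extent")
  if (n == 1L) return(f[word])
  pl <- .cc_plan(n)
  m <- matrix(0, pl$n_masks, 1L)
  for (mask in seq_len(pl$n_masks)) {
    bits <- pl$bits_of[[mask]]
    marg <- apply(f, bits, sum)
    m[mask, 1L] <- marg[matrix(word[bits], nrow = 1L)]
  }
  .cumulants(m, n)[pl$n_masks, 1L]
}
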