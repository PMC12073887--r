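#' Single-site and bivariate marginal frequencies with pseudocount
#'
#' Empirical frequencies are blended with the uniform distribution:
#' `f <- (1 - w) * f_emp + w * u` with `u = 1/q` (single-site) or `1/q^2`
#' (bivariate) and weight `w = Npc / (N + Npc)` for `Npc = scale * N`
#' pseudo-observations. A scale of `1/N` therefore adds a single uniform
#' pseudo-observation (`w = 1/(N + 1)`), the conventional regularization
#' ahead of coupling inference. Blending both orders with the same `w`
#' keeps the marginalization identity: row/column sums of each bivariate
#' table equal the pseudocounted single-site frequencies.
#'
#' @param msa An [encoded_msa].
#' @param pseudocount_scale Nonnegative scale; `0` gives raw empirical
#'   frequencies.
#' @return List of class `"marginal_set"`: `f1` (`L x q`), `f2`
#'   (`q x q x npair` array over column pairs in canonical `(i<j)` order),
#'   `pseudocount_scale`, `n_source`, `L`, `q`.
#' @export
estimate_marginals <- function(msa, pseudocount_scale = 0) {
  stopifnot(inherits(msa, "encoded_msa"))
  if (!is.numeric(pseudocount_scale) || pseudocount_scale < 0) {
    stop("`pseudocount_scale` must be nonnegative")
  }
  codes <- msa$codes
  N <- nrow(codes)
  L <- ncol(codes)
  q <- length(msa$alphabet)
  f1 <- t(vapply(seq_len(L),
                 function(i) tabulate(codes[, i], nbins = q) / N,
                 numeric(q)))
  f2 <- cpp_pair_counts(codes, q) / N
  w <- pseudocount_scale / (1 + pseudocount_scale)
  if (w > 0) {
    f1 <- (1 - w) * f1 + w / q
    f2 <- (1 - w) * f2 + w / q^2
  }
  structure(list(f1 = f1, f2 = f2, pseudocount_scale = pseudocount_scale,
                 n_source = N, L = L, q = q),
            class = "marginal_set")
}

#' @export
print.marginal_set <- function(x, ...) {
  cat(sprintf(paste0("Marginal set: L = %d, q = %d, from %d sequences ",
                     "(pseudocount scale %.3g)\n"),
              x$L, x$q, x$n_source, x$pseudocount_scale))
  invisible(x)
}

#' Pairwise connected correlations (covariations) of an MSA
#'
#' `C[a, b, (i,j)] = f2[a, b, (i,j)] - f1[i, a] * f1[j, b]`, the excess of
#' the joint frequency over the product of the site frequencies, computed
#' from plug-in (pseudocount-free) estimates. The summary statistic
#' `mean(abs(pair_covariation(msa)))` is the standard probe for
#' phylogenetically induced spurious covariation.
#'
#' @param msa An [encoded_msa].
#' @return `q x q x npair` array of connected pairwise correlations.
#' @export
pair_covariation <- function(msa) {
  m <- estimate_marginals(msa, pseudocount_scale = 0)
  pairs <- .pair_table(m$L)
  C <- m$f2
  for (p in seq_len(nrow(pairs))) {
    C[, , p] <- C[, , p] - outer(m$f1[pairs[p, 1L], ], m$f1[pairs[p, 2L], ])
  }
  C
}
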