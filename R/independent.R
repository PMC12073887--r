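#' Fit a site-independent model
#'
#' The site-independent model `P(S) = Π_i f1[i, s_i]` uses the
#' (pseudocounted) single-site frequencies of the training alignment and
#' ignores all covariation — by construction its connected correlations
#' vanish at every order, which makes it the standard baseline for
#' covariation-sensitive evaluation metrics.
#'
#' @param msa An [encoded_msa].
#' @param pseudocount_scale Pseudocount scale (see [estimate_marginals()]);
#'   default 0.
#' @return Object of class `"indep_model"` with the `L x q` frequency
#'   table `f1`.
#' @export
fit_independent <- function(msa, pseudocount_scale = 0) {
  stopifnot(inherits(msa, "encoded_msa"))
  marg <- estimate_marginals(msa, pseudocount_scale)
  structure(list(f1 = marg$f1, L = marg$L, q = marg$q,
                 pseudocount_scale = pseudocount_scale,
                 alphabet = msa$alphabet),
            class = "indep_model")
}

#' Draw sequences from a site-independent model
#'
#' Each column is drawn independently from its frequency vector.
#'
#' @param model An `"indep_model"` from [fit_independent()].
#' @param n_seq Number of sequences.
#' @param seed Integer seed.
#' @return An [encoded_msa].
#' @export
sample_independent <- function(model, n_seq, seed = NULL) {
  stopifnot(inherits(model, "indep_model"))
  n_seq <- .check_count(n_seq, "n_seq")
  .with_seed(seed, {
    codes <- vapply(seq_len(model$L), function(i) {
      sample.int(model$q, n_seq, replace = TRUE, prob = model$f1[i, ])
    }, integer(n_seq))
    if (n_seq == 1L) codes <- matrix(codes, nrow = 1L)
    encoded_msa(codes, alphabet = model$alphabet)
  })
}

#' @rdname sample_independent
#' @param object,nsim,... `simulate` method arguments.
#' @export
simulate.indep_model <- function(object, nsim = 1, seed = NULL, ...) {
  sample_independent(object, n_seq = nsim, seed = seed)
}

#' @export
print.indep_model <- function(x, ...) {
  cat(sprintf(paste0("Site-independent model: L = %d, q = %d ",
                     "(pseudocount scale %.3g)\n"),
              x$L, x$q, x$pseudocount_scale))
  invisible(x)
}

#' @export
#' @method coef indep_model
coef.indep_model <- function(object, ...) object$f1
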