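#' Construct a Potts model from explicit parameters
#'
#' A Potts model assigns each aligned sequence `S` the Boltzmann
#' probability `P(S) ∝ exp(-E(S))` with energy
#' `E(S) = Σ_{i<j} J[s_i, s_j, (i,j)] + Σ_i h[i, s_i]`.
#' Couplings are stored as a `q x q x npair` array over column pairs in
#' canonical `(i<j)` order; site fields `h` are optional (with couplings
#' on every pair they are absorbable by a gauge transformation).
#'
#' @param J Coupling array `q x q x L(L-1)/2`, finite.
#' @param h Optional `L x q` field matrix.
#' @param alphabet An [aa_alphabet()] with `q` states.
#' @param gauge Gauge tag, `"raw"` or `"zero-sum"`.
#' @return An object of class `"potts"`.
#' @seealso [fit_potts()], [random_potts()], [zero_sum_gauge()],
#'   [sample_potts()]
#' @export
potts_model <- function(J, h = NULL, alphabet = NULL, gauge = "raw") {
  J <- as.array(J)
  d <- dim(J)
  if (length(d) != 3L || d[1L] != d[2L]) {
    stop("`J` must be a q x q x npair array")
  }
  q <- d[1L]
  L <- as.integer(round((1 + sqrt(1 + 8 * d[3L])) / 2))
  if ((L * (L - 1L)) %/% 2L != d[3L]) {
    stop("third dimension of `J` is not L*(L-1)/2")
  }
  if (!all(is.finite(J))) stop("`J` must be finite")
  if (!is.null(h)) {
    h <- as.matrix(h)
    if (!identical(dim(h), c(L, q))) stop("`h` must be L x q")
    if (!all(is.finite(h))) stop("`h` must be finite")
  }
  if (is.null(alphabet)) alphabet <- aa_alphabet(q)
  if (length(alphabet) != q) stop("alphabet size does not match q")
  structure(list(L = L, q = q, J = J, h = h, alphabet = alphabet,
                 gauge = gauge, fit = NULL),
            class = "potts")
}

#' Potts energy of sequences
#'
#' `E(S) = Σ_{i<j} J[s_i, s_j, (i,j)] (+ Σ_i h[i, s_i])`; lower energy
#' means higher probability, `P(S) ∝ exp(-E)`.
#'
#' @param model A `potts` model.
#' @param x An [encoded_msa] or an integer code matrix/vector with `L`
#'   columns.
#' @return Numeric vector of energies, one per sequence.
#' @export
potts_energy <- function(model, x) {
  stopifnot(inherits(model, "potts"))
  codes <- if (inherits(x, "encoded_msa")) x$codes else {
    if (is.null(dim(x))) matrix(as.integer(x), nrow = 1L) else as.matrix(x)
  }
  storage.mode(codes) <- "integer"
  if (ncol(codes) != model$L) stop("sequence length does not match model L")
  if (any(codes < 1L | codes > model$q)) stop("codes outside 1..q")
  cpp_energies(codes, model$J, model$h, model$q)
}

#' Transform a Potts model to the zero-sum gauge
#'
#' Per coupling block the row and column means are shifted to zero; the
#' removed single-site parts are absorbed into explicit fields (created if
#' absent) so that sequence probabilities are unchanged. The zero-sum
#' gauge is the conventional normal form for comparing coupling matrices
#' across fits.
#'
#' @param model A `potts` model.
#' @return The gauge-fixed `potts` model (`gauge = "zero-sum"`).
#' @export
zero_sum_gauge <- function(model) {
  stopifnot(inherits(model, "potts"))
  L <- model$L; q <- model$q
  J <- model$J
  pairs <- .pair_table(L)
  dh <- matrix(0, L, q)
  for (p in seq_len(nrow(pairs))) {
    B <- J[, , p]
    rm <- rowMeans(B); cm <- colMeans(B); m <- mean(B)
    J[, , p] <- B - outer(rm, rep(1, q)) - outer(rep(1, q), cm) + m
    dh[pairs[p, 1L], ] <- dh[pairs[p, 1L], ] + (rm - m)
    dh[pairs[p, 2L], ] <- dh[pairs[p, 2L], ] + (cm - m)
  }
  h <- model$h
  if (is.null(h)) {
    if (max(abs(dh)) > 1e-12) h <- dh
  } else {
    h <- h + dh
  }
  if (!is.null(h)) h <- h - rowMeans(h)  # drop per-site constants
  out <- model
  out$J <- J
  out$h <- h
  out$gauge <- "zero-sum"
  out
}

#' Draw sequences from a Potts model by MCMC
#'
#' Runs one independent single-site Metropolis chain per requested
#' sequence (uniform state proposals, sequential site sweeps), each
#' initialized from a uniform random sequence unless `init` is given, and
#' returns the final states. When `nsweeps` is `NULL` the chain length is
#' chosen by an equilibration check: sweeps proceed in batches until the
#' mean energy of two consecutive batches agrees within twice its
#' combined standard error, after which one further batch is run.
#'
#' @param model A `potts` model.
#' @param n_seq Number of sequences (chains).
#' @param nsweeps Full sweeps per chain, or `NULL` for the adaptive check.
#' @param seed Integer seed; identical seeds reproduce the MSA exactly.
#' @param init Optional [encoded_msa] or code matrix of starting states
#'   (recycled rows not allowed; must have `n_seq` rows).
#' @param batch Sweeps per batch for the adaptive check.
#' @param max_sweeps Cap for the adaptive check (warned when hit).
#' @return An [encoded_msa]; attribute `"nsweeps"` records the sweeps run.
#' @export
sample_potts <- function(model, n_seq, nsweeps = NULL, seed = NULL,
                         init = NULL, batch = 64L, max_sweeps = 4096L) {
  stopifnot(inherits(model, "potts"))
  n_seq <- .check_count(n_seq, "n_seq")
  L <- model$L; q <- model$q
  .with_seed(seed, {
    if (is.null(init)) {
      codes <- matrix(sample.int(q, n_seq * L, replace = TRUE), n_seq, L)
    } else {
      codes <- if (inherits(init, "encoded_msa")) init$codes else as.matrix(init)
      if (nrow(codes) != n_seq || ncol(codes) != L) {
        stop("`init` must be n_seq x L")
      }
    }
    storage.mode(codes) <- "integer"
    if (!is.null(nsweeps)) {
      nsweeps <- .check_count(nsweeps, "nsweeps", min = 0L)
      if (nsweeps > 0L) {
        codes <- cpp_sample_potts(codes, model$J, model$h, q, nsweeps)
      }
      total <- nsweeps
    } else {
      total <- 0L
      e_prev <- NULL
      repeat {
        codes <- cpp_sample_potts(codes, model$J, model$h, q, batch)
        total <- total + batch
        e <- cpp_energies(codes, model$J, model$h, q)
        if (!is.null(e_prev)) {
          se <- sqrt(var(e) / length(e) + var(e_prev) / length(e_prev))
          if (abs(mean(e) - mean(e_prev)) <= 2 * se) {
            codes <- cpp_sample_potts(codes, model$J, model$h, q, batch)
            total <- total + batch
            break
          }
        }
        e_prev <- e
        if (total >= max_sweeps) {
          warning(sprintf("equilibration check not passed within %d sweeps",
                          max_sweeps))
          break
        }
      }
    }
    out <- encoded_msa(codes, alphabet = model$alphabet)
    attr(out, "nsweeps") <- total
    out
  })
}

#' @rdname sample_potts
#' @param object A `potts` model (for the `simulate` method).
#' @param nsim Number of sequences to draw.
#' @param ... Passed on to [sample_potts()].
#' @export
simulate.potts <- function(object, nsim = 1, seed = NULL, ...) {
  sample_potts(object, n_seq = nsim, seed = seed, ...)
}

#' Fit a Potts model by marginal matching
#'
#' Estimates pairwise couplings so that the model's bivariate marginals
#' reproduce the (pseudocounted) bivariate marginals of the training
#' alignment — the Boltzmann-machine maximum-likelihood condition, with
#' gradient `ΔJ ∝ f2(model) - f2(data)`. Two gradient back-ends are
#' available: exact enumeration of the sequence space (`q^L` small), and
#' persistent-chain MCMC where each iteration advances a population of
#' Metropolis chains a few sweeps and uses their empirical marginals as
#' the model estimate. The returned model is in the zero-sum gauge.
#'
#' The MCMC back-end runs two phases. A search phase iterates until the
#' smoothed mean absolute marginal deviation falls below `tol` times the
#' finite-sampling noise floor of the chain population (the expected
#' deviation of a perfectly fitted model estimated from `n_chains`
#' samples). A refinement phase then enlarges the chain population by
#' `refine_factor`, decays the step size (Robbins–Monro style), and
#' returns couplings averaged over the tail of the trajectory, which
#' strips most optimizer noise and pushes the model's marginal error
#' well below the training MSA's own sampling noise. The enumeration
#' back-end uses an absolute deviation tolerance with backtracking line
#' search.
#'
#' @param x An [encoded_msa] or a `"marginal_set"` from
#'   [estimate_marginals()].
#' @param pseudocount_scale Pseudocount scale for the training marginals;
#'   default `1/N` (one uniform pseudo-observation). Ignored when `x` is
#'   already a marginal set.
#' @param method `"auto"` (enumeration when `q^L <= 1e5`), `"enumerate"`,
#'   or `"mcmc"`.
#' @param n_chains MCMC chain population per gradient estimate.
#' @param sweeps_per_iter Metropolis sweeps between gradient steps.
#' @param lr Initial learning rate; default `0.25 * q` (MCMC) or `q`
#'   (enumeration).
#' @param maxit Maximum gradient iterations.
#' @param tol MCMC: multiple of the noise floor at which the search
#'   phase stops (default 3). Enumeration: absolute mean |deviation|
#'   target (default 1e-6).
#' @param refine Refinement iterations after MCMC convergence; couplings
#'   are averaged over the tail two-thirds.
#' @param refine_factor Chain-population multiplier for the refinement
#'   phase.
#' @param l2 Optional ridge penalty on `J` (default 0).
#' @param alphabet Alphabet for models fit from a bare marginal set.
#' @param seed Seed for the MCMC chains.
#' @param verbose Print progress every 25 iterations.
#' @return A fitted `potts` model (zero-sum gauge). Component `fit`
#'   records the back-end, iteration count, final mean absolute marginal
#'   deviation and noise floor, the training marginals, the model
#'   marginals at the fitted parameters, and their difference
#'   (`residuals`). Non-convergence raises an error carrying the final
#'   deviation.
#' @export
fit_potts <- function(x, pseudocount_scale = NULL,
                      method = c("auto", "enumerate", "mcmc"),
                      n_chains = 4000L, sweeps_per_iter = 5L, lr = NULL,
                      maxit = NULL, tol = NULL, refine = 150L,
                      refine_factor = 4L, l2 = 0,
                      alphabet = NULL, seed = NULL, verbose = FALSE) {
  method <- match.arg(method)
  if (inherits(x, "encoded_msa")) {
    if (is.null(pseudocount_scale)) pseudocount_scale <- 1 / nrow(x$codes)
    marg <- estimate_marginals(x, pseudocount_scale)
    if (is.null(alphabet)) alphabet <- x$alphabet
  } else if (inherits(x, "marginal_set")) {
    marg <- x
  } else {
    stop("`x` must be an encoded_msa or a marginal_set")
  }
  L <- marg$L; q <- marg$q
  if (is.null(alphabet)) alphabet <- aa_alphabet(q)
  f2d <- marg$f2
  if (min(f2d) <= 0) {
    stop(paste("training bivariate marginals contain zeros;",
               "use a positive pseudocount_scale"))
  }
  if (method == "auto") {
    method <- if (q^L <= 1e5) "enumerate" else "mcmc"
  }
  npair <- (L * (L - 1L)) %/% 2L
  J <- array(0, dim = c(q, q, npair))

  if (method == "enumerate") {
    if (is.null(lr)) lr <- q
    if (is.null(maxit)) maxit <- 2000L
    if (is.null(tol)) tol <- 1e-6
    states <- enumerate_states(L, q)
    model_f2 <- function(J) {
      E <- cpp_energies(states, J, NULL, q)
      w <- exp(-(E - min(E)))
      cpp_pair_counts_weighted(states, w / sum(w), q)
    }
    f2m <- model_f2(J)
    cur <- list(J = J, mad = mean(abs(f2m - f2d)), f2m = f2m)
    best <- cur
    v <- array(0, dim = dim(J))       # heavy-ball momentum for the
    beta <- 0.85                      # ill-conditioned tail of the fit
    it <- 0L
    while (it < maxit && best$mad > tol) {
      it <- it + 1L
      v <- beta * v + (cur$f2m - f2d) - l2 * cur$J
      Jtry <- cur$J + lr * v
      f2m <- model_f2(Jtry)
      mad <- mean(abs(f2m - f2d))
      if (mad < cur$mad * 1.2) {      # tolerate momentum overshoot
        cur <- list(J = Jtry, mad = mad, f2m = f2m)
        if (mad < best$mad) best <- cur
        lr <- lr * 1.05
      } else {
        cur <- best
        v[] <- 0
        lr <- lr / 2
        if (lr < 1e-8) break
      }
      if (verbose && it %% 25L == 0L) {
        message(sprintf("iter %d: mad %.3g (lr %.3g)", it, best$mad, lr))
      }
    }
    if (best$mad > tol) {
      stop(sprintf(paste("marginal matching did not converge: mean",
                         "|deviation| %.3g after %d iterations"),
                   best$mad, it))
    }
    fit <- list(method = "enumerate", iterations = it, mad = best$mad,
                noise_floor = 0, converged = TRUE,
                pseudocount_scale = marg$pseudocount_scale,
                data_marginals = f2d, model_marginals = best$f2m,
                residuals = best$f2m - f2d, n_chains = NA_integer_)
    J <- best$J
  } else {
    if (is.null(lr)) lr <- 0.25 * q
    if (is.null(maxit)) maxit <- 600L
    if (is.null(tol)) tol <- 3
    n_chains <- .check_count(n_chains, "n_chains")
    floor_ <- sqrt(2 / pi) * mean(sqrt(f2d * (1 - f2d) / n_chains))
    target <- tol * floor_
    .with_seed(seed, {
      chains <- matrix(sample.int(q, n_chains * L, replace = TRUE),
                       n_chains, L)
      storage.mode(chains) <- "integer"
      mad_ema <- NA_real_
      it <- 0L
      converged <- FALSE
      while (it < maxit) {
        it <- it + 1L
        chains <- cpp_sample_potts(chains, J, NULL, q, sweeps_per_iter)
        f2m <- cpp_pair_counts(chains, q) / n_chains
        g <- f2m - f2d
        mad <- mean(abs(g))
        mad_ema <- if (is.na(mad_ema)) mad else 0.9 * mad_ema + 0.1 * mad
        step <- lr / (1 + it / 200)
        J <- J + step * g - step * l2 * J
        if (verbose && it %% 25L == 0L) {
          message(sprintf("iter %d: mad %.3g (target %.3g)", it, mad_ema,
                          target))
        }
        if (it > 20L && mad_ema <= target) {
          converged <- TRUE
          break
        }
      }
      if (!converged) {
        stop(sprintf(paste("marginal matching did not converge: mean",
                           "|deviation| %.3g vs target %.3g after %d",
                           "iterations"), mad_ema, target, it))
      }
      # refinement: larger population, decaying steps, tail-averaged J
      refine <- .check_count(refine, "refine", min = 1L)
      n_ref <- n_chains * .check_count(refine_factor, "refine_factor")
      chains <- chains[rep(seq_len(n_chains), length.out = n_ref), ,
                       drop = FALSE]
      chains <- cpp_sample_potts(chains, J, NULL, q, 4L * sweeps_per_iter)
      Jbar <- array(0, dim = dim(J))
      n_avg <- 0L
      burn <- refine %/% 3L
      for (k in seq_len(refine)) {
        chains <- cpp_sample_potts(chains, J, NULL, q, sweeps_per_iter)
        f2m <- cpp_pair_counts(chains, q) / n_ref
        J <- J + (lr / 8 / (1 + k / 30)) * (f2m - f2d)
        if (k > burn) {
          Jbar <- Jbar + J
          n_avg <- n_avg + 1L
        }
      }
      J <- Jbar / n_avg
      chains <- cpp_sample_potts(chains, J, NULL, q, 4L * sweeps_per_iter)
      f2m <- cpp_pair_counts(chains, q) / n_ref
      fit <- list(method = "mcmc", iterations = it + refine,
                  mad = mean(abs(f2m - f2d)), noise_floor = floor_,
                  converged = TRUE,
                  pseudocount_scale = marg$pseudocount_scale,
                  data_marginals = f2d, model_marginals = f2m,
                  residuals = f2m - f2d, n_chains = n_ref)
    })
  }
  model <- potts_model(J, h = NULL, alphabet = alphabet, gauge = "raw")
  model <- zero_sum_gauge(model)
  model$fit <- fit
  model$call <- match.call()
  model
}

#' @export
print.potts <- function(x, ...) {
  cat(sprintf("Potts model: L = %d, q = %d (%s gauge)\n", x$L, x$q, x$gauge))
  if (!is.null(x$fit)) {
    cat(sprintf(paste0("  fitted by marginal matching (%s back-end), ",
                       "%d iterations\n",
                       "  mean |f2 model - data| = %.3g",
                       " (noise floor %.3g)\n"),
        x$fit$method, x$fit$iterations, x$fit$mad, x$fit$noise_floor))
  }
  invisible(x)
}

#' @export
#' @method summary potts
summary.potts <- function(object, ...) {
  pairs <- .pair_table(object$L)
  fro <- vapply(seq_len(dim(object$J)[3L]),
                function(p) sqrt(sum(object$J[, , p]^2)), numeric(1))
  structure(list(L = object$L, q = object$q, gauge = object$gauge,
                 coupling_norms = data.frame(i = pairs[, 1L],
                                             j = pairs[, 2L],
                                             frobenius = fro),
                 fit = object$fit),
            class = "summary.potts")
}

#' @export
print.summary.potts <- function(x, ...) {
  cat(sprintf("Potts model: L = %d, q = %d (%s gauge)\n", x$L, x$q, x$gauge))
  cat("Per-pair coupling Frobenius norms:\n")
  print(summary(x$coupling_norms$frobenius))
  top <- head(x$coupling_norms[order(-x$coupling_norms$frobenius), ], 5L)
  cat("Strongest pairs:\n")
  print(top, row.names = FALSE)
  if (!is.null(x$fit)) {
    cat(sprintf("Fit: %s, %d iterations, mean |residual| %.3g\n",
                x$fit$method, x$fit$iterations, x$fit$mad))
  }
  invisible(x)
}

#' @export
#' @method coef potts
coef.potts <- function(object, ...) object$J

#' @param type `"energy"` (default) or `"logprob"` (requires `q^L <= 1e6`
#'   for the partition function).
#' @rdname potts_energy
#' @param object,newdata,... `predict` method arguments: a fitted model
#'   and an [encoded_msa] (or code matrix).
#' @export
predict.potts <- function(object, newdata, type = c("energy", "logprob"),
                          ...) {
  type <- match.arg(type)
  e <- potts_energy(object, newdata)
  if (type == "energy") return(e)
  d <- exact_distribution(object)
  -e - d$logZ
}

#' @export
#' @method residuals potts
residuals.potts <- function(object, ...) {
  if (is.null(object$fit)) {
    stop("model was not fitted (no marginal residuals available)")
  }
  object$fit$residuals
}

#' @export
#' @method plot potts
plot.potts <- function(x, ...) {
  if (is.null(x$fit)) stop("plot method requires a fitted model")
  fd <- as.vector(x$fit$data_marginals)
  fm <- as.vector(x$fit$model_marginals)
  graphics::plot(fd, fm, pch = ".", col = "#00000055",
                 xlab = "training bivariate marginal",
                 ylab = "model bivariate marginal",
                 main = "Marginal matching", ...)
  graphics::abline(0, 1, col = 2)
  invisible(x)
}
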