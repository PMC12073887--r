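#' Pairwise sequence identity
#'
#' Identity is the fraction of alignment columns at which two rows carry
#' the same code. By default the gap is an ordinary 21st matchable state
#' (gap aligned to gap counts as a match); `gaps = "exclude"` instead
#' drops columns where either row is gapped and divides by the remaining
#' column count (0 if none remain).
#'
#' @param msa An [encoded_msa].
#' @param gaps `"match"` (default) or `"exclude"`.
#' @return Symmetric `N x N` matrix of identities in `[0, 1]`.
#' @export
pairwise_identity <- function(msa, gaps = c("match", "exclude")) {
  stopifnot(inherits(msa, "encoded_msa"))
  gaps <- match.arg(gaps)
  cpp_identity_matrix(msa$codes, gaps == "exclude",
                      length(msa$alphabet))
}

#' Identity between two code rows
#'
#' @param a,b Integer code vectors of equal length.
#' @param gap_code Gap code used when `gaps = "exclude"`.
#' @inheritParams pairwise_identity
#' @return Fraction in `[0, 1]`.
#' @export
seq_identity <- function(a, b, gaps = c("match", "exclude"), gap_code = 21L) {
  gaps <- match.arg(gaps)
  if (length(a) != length(b)) stop("sequences have different lengths")
  if (gaps == "match") return(mean(a == b))
  keep <- a != gap_code & b != gap_code
  if (!any(keep)) return(0)
  mean(a[keep] == b[keep])
}

#' Filter an MSA at an identity threshold
#'
#' Pairs of sequences more similar than `threshold` are found and one
#' member of each pair is dropped at random, approximating an i.i.d.
#' sample by removing phylogenetic redundancy. Offending pairs are visited
#' in lexicographic `(i, j)` order over the original rows; when both
#' members are still alive, the seeded RNG drops one. The guaranteed
#' postcondition is that no surviving pair exceeds the threshold — every
#' offending pair is visited at least once, so at least one member of each
#' is removed. Survivors keep their original order.
#'
#' @param msa An [encoded_msa].
#' @param threshold Identity threshold in `(0, 1)`; survivors have
#'   pairwise identity `<= threshold`. The conventional value is 0.5; the
#'   0.6 and 0.9 cutoffs are common robustness checks.
#' @param seed Integer seed for the drop decisions, or `NULL` to use the
#'   current RNG stream.
#' @inheritParams pairwise_identity
#' @return List of class `"identity_filter"`: `msa` (survivors), `keep`
#'   (surviving row indices), `threshold`, and `identity` (the full input
#'   identity matrix, reused by [phylo_split()]).
#' @export
identity_filter <- function(msa, threshold = 0.5, seed = NULL,
                            gaps = c("match", "exclude")) {
  stopifnot(inherits(msa, "encoded_msa"))
  gaps <- match.arg(gaps)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0, 1)")
  }
  idm <- pairwise_identity(msa, gaps = gaps)
  keep <- .filter_on_identity(idm, threshold, seed)
  structure(list(msa = `[.encoded_msa`(msa, keep), keep = keep,
                 threshold = threshold, identity = idm),
            class = "identity_filter")
}

.filter_on_identity <- function(idm, threshold, seed) {
  N <- nrow(idm)
  above <- which(upper.tri(idm) & idm > threshold, arr.ind = TRUE)
  if (nrow(above) == 0L) return(seq_len(N))
  above <- above[order(above[, 1L], above[, 2L]), , drop = FALSE]
  alive <- rep(TRUE, N)
  .with_seed(seed, {
    for (k in seq_len(nrow(above))) {
      i <- above[k, 1L]; j <- above[k, 2L]
      if (alive[i] && alive[j]) {
        alive[if (runif(1L) < 0.5) i else j] <- FALSE
      }
    }
  })
  which(alive)
}

#' @export
print.identity_filter <- function(x, ...) {
  cat(sprintf("Identity filter at %.0f%%: %d of %d sequences survive\n",
              100 * x$threshold, length(x$keep), nrow(x$identity)))
  invisible(x)
}

#' Phylogeny-aware training/reference split
#'
#' The MSA is first identity-filtered, the survivors are randomly
#' partitioned into a training and a reference half, and every dropped
#' (unfiltered) sequence is then assigned to the half containing its most
#' similar survivor, so clusters of closely related sequences end up on
#' one side of the split and never straddle it. Ties in similarity are
#' broken by the lowest survivor index.
#'
#' @inheritParams identity_filter
#' @param train_size,ref_size Sizes of the two survivor halves; default is
#'   an equal split with any odd survivor going to training.
#' @param seed Integer seed covering both the filter drops and the random
#'   partition.
#' @return List of class `"phylo_split"`: `training_idx` and
#'   `reference_idx` (indices into the source MSA, survivors plus assigned
#'   relatives), `train_survivors`, `ref_survivors`, `assignment` (factor
#'   over all source rows), `nearest` (most similar survivor per row),
#'   `keep`, `threshold`, `seed`.
#' @export
phylo_split <- function(msa, threshold = 0.5, train_size = NULL,
                        ref_size = NULL, seed = NULL,
                        gaps = c("match", "exclude")) {
  gaps <- match.arg(gaps)
  flt <- identity_filter(msa, threshold = threshold, seed = seed, gaps = gaps)
  keep <- flt$keep
  n_surv <- length(keep)
  if (n_surv < 2L) stop("need at least 2 filtered survivors to split")
  if (is.null(train_size) && is.null(ref_size)) {
    ref_size <- n_surv %/% 2L
    train_size <- n_surv - ref_size   # odd survivor goes to training
  } else {
    train_size <- .check_count(train_size, "train_size")
    ref_size <- .check_count(ref_size, "ref_size")
  }
  if (train_size + ref_size > n_surv) {
    stop(sprintf("requested half sizes (%d + %d) exceed survivor count (%d)",
                 train_size, ref_size, n_surv))
  }
  perm <- .with_seed(if (is.null(seed)) NULL else seed + 1L,
                     sample.int(n_surv))
  train_survivors <- sort(keep[perm[seq_len(train_size)]])
  ref_survivors <- sort(keep[perm[train_size + seq_len(ref_size)]])
  used <- sort(c(train_survivors, ref_survivors))

  N <- nrow(msa$codes)
  idm <- flt$identity
  half <- integer(N)            # 1 = training, 2 = reference
  half[train_survivors] <- 1L
  half[ref_survivors] <- 2L
  nearest <- integer(N)
  nearest[used] <- used
  others <- setdiff(seq_len(N), used)
  if (length(others) > 0L) {
    sim <- idm[others, used, drop = FALSE]
    best <- max.col(sim, ties.method = "first")  # lowest survivor index wins
    nearest[others] <- used[best]
    half[others] <- half[used[best]]
  }
  structure(list(
    training_idx = which(half == 1L),
    reference_idx = which(half == 2L),
    train_survivors = train_survivors,
    ref_survivors = ref_survivors,
    assignment = factor(c("training", "reference")[half],
                        levels = c("training", "reference")),
    nearest = nearest,
    keep = keep, threshold = threshold, seed = seed
  ), class = "phylo_split")
}

#' @export
print.phylo_split <- function(x, ...) {
  cat(sprintf(paste0(
    "Phylogeny-aware split at %.0f%% identity\n",
    "  survivors: %d training + %d reference\n",
    "  with assigned relatives: %d training / %d reference\n"),
    100 * x$threshold, length(x$train_survivors), length(x$ref_survivors),
    length(x$training_idx), length(x$reference_idx)))
  invisible(x)
}
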