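# Higher-order marginal (HOM) statistics: a "word" is the joint state of a
# sequence at a chosen set of n columns; r20 compares word frequencies
# between a reference and an evaluation MSA over the 20 most common
# reference words, averaged over many random column sets.

#' Draw random position sets
#'
#' Draws `count` distinct column sets of size `order` uniformly (without
#' within-set replacement). When fewer than `count` distinct sets exist,
#' all `choose(L, order)` sets are returned once each.
#'
#' @param L Number of alignment columns.
#' @param order Set size `n` (`2 <= order <= L`).
#' @param count Number of sets requested.
#' @param seed Integer seed.
#' @return Integer matrix, one sorted position set per row.
#' @export
sample_position_sets <- function(L, order, count = 3000L, seed = NULL) {
  L <- .check_count(L, "L")
  order <- .check_count(order, "order")
  count <- .check_count(count, "count")
  if (order > L) stop("`order` exceeds the number of columns")
  n_all <- choose(L, order)
  if (n_all <= count) {
    return(t(utils::combn(L, order)))
  }
  .with_seed(seed, {
    seen <- new.env(hash = TRUE)
    out <- matrix(0L, count, order)
    got <- 0L
    while (got < count) {
      s <- sort(sample.int(L, order))
      key <- paste(s, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1L
        out[got, ] <- s
      }
    }
    out
  })
}

#' Pre-draw position sets for a family of orders
#'
#' Drawing the sets once and passing them to every [r20()] call makes
#' model comparisons share identical column sets, removing one source of
#' variance between arms of an experiment.
#'
#' @inheritParams sample_position_sets
#' @param orders Integer vector of word sizes.
#' @param n_sets Sets per order.
#' @return Named list (one matrix per order) of class `"position_sets"`.
#' @export
position_sets <- function(L, orders = 2:8, n_sets = 3000L, seed = NULL) {
  orders <- vapply(orders, .check_count, integer(1), name = "orders")
  .with_seed(seed, {
    out <- lapply(orders, function(n) sample_position_sets(L, n, n_sets))
    names(out) <- as.character(orders)
    structure(out, L = L, class = "position_sets")
  })
}

# word ids: position 1 most significant so numeric order == lexicographic
# word order (used for deterministic tie-breaks at the top-k boundary)
.word_ids <- function(codes, cols, q) {
  n <- length(cols)
  pw <- q^((n - 1L):0L)
  as.vector((codes[, cols, drop = FALSE] - 1) %*% pw)
}

.id_to_word <- function(id, n, q) {
  w <- integer(n)
  for (k in n:1) {
    w[k] <- id %% q
    id <- id %/% q
  }
  as.integer(w) + 1L
}

.count_ids <- function(ids) {
  o <- sort.int(ids, method = "quick")
  r <- rle(o)
  list(values = r$values, counts = r$lengths)
}

.freq_of <- function(ids, wanted) {
  tabulate(match(ids, wanted), nbins = length(wanted)) / length(ids)
}

#' Word frequencies at a position set
#'
#' @param msa An [encoded_msa].
#' @param columns Sorted column indices (the position set).
#' @param words Optional list/matrix of code tuples. When omitted, all
#'   observed words are returned with their frequencies, most frequent
#'   first (ties in lexicographic word order); when given, the frequency
#'   of each requested word (0 if absent).
#' @return Data frame with a `word` string column (alphabet characters)
#'   and `freq`.
#' @export
word_frequencies <- function(msa, columns, words = NULL) {
  stopifnot(inherits(msa, "encoded_msa"))
  columns <- as.integer(columns)
  if (any(columns < 1L) || any(columns > ncol(msa$codes))) {
    stop("`columns` out of range")
  }
  q <- length(msa$alphabet)
  n <- length(columns)
  ids <- .word_ids(msa$codes, columns, q)
  to_str <- function(wm) {
    apply(matrix(unclass(msa$alphabet)[wm], ncol = n), 1L, paste0,
          collapse = "")
  }
  if (is.null(words)) {
    ct <- .count_ids(ids)
    ord <- order(-ct$counts, ct$values)
    wm <- t(vapply(ct$values[ord], .id_to_word, integer(n), n = n, q = q))
    data.frame(word = to_str(wm), freq = ct$counts[ord] / length(ids),
               stringsAsFactors = FALSE)
  } else {
    wm <- if (is.matrix(words)) words else do.call(rbind, words)
    wids <- .word_ids(wm, seq_len(n), q)
    data.frame(word = to_str(wm), freq = .freq_of(ids, wids),
               stringsAsFactors = FALSE)
  }
}

#' r20 and connected-correlation r20 between two MSAs
#'
#' For each order `n`, random position sets are drawn (or taken from
#' `position_sets`); for each set the `top_k` most frequent words in the
#' *reference* MSA are found (ties at the boundary broken by
#' lexicographic word order) and the Pearson correlation between the
#' reference and evaluation statistics of those words is computed. The
#' per-order mean over retained sets is the r20 value. With
#' `metric = "connected"` the compared statistic is each word's connected
#' correlation (Ursell function) instead of its raw frequency — the
#' cc-r20 metric, which discounts everything explainable by lower-order
#' structure. Sets where either statistic vector has zero variance are
#' skipped and counted.
#'
#' @param reference,evaluation [encoded_msa] objects over the same
#'   columns and alphabet. The reference defines the word lists.
#' @param orders Word sizes to evaluate; default 2:8, or every order
#'   covered by `position_sets` when those are supplied.
#' @param n_sets Position sets per order (default 3000).
#' @param top_k Words per set (default 20).
#' @param seed Seed for the position-set draw.
#' @param position_sets Optional [position_sets()] list to reuse across
#'   model arms.
#' @param metric `"frequency"` (r20) or `"connected"` (cc-r20).
#' @param exclude_allgap Drop the all-gap word from the reference top-k.
#' @return Object of class `"r20_result"`: `summary` data frame (order,
#'   mean_r, n_sets, n_used, n_skipped), `per_set` correlations,
#'   `metric`, and the position sets used.
#' @export
r20 <- function(reference, evaluation, orders = NULL, n_sets = 3000L,
                top_k = 20L, seed = NULL, position_sets = NULL,
                metric = c("frequency", "connected"),
                exclude_allgap = FALSE) {
  metric <- match.arg(metric)
  if (is.null(orders)) {
    orders <- if (is.null(position_sets)) 2:8 else
      as.integer(names(position_sets))
  }
  stopifnot(inherits(reference, "encoded_msa"),
            inherits(evaluation, "encoded_msa"))
  if (!.same_frame(reference, evaluation)) {
    stop("reference and evaluation MSAs must share L and alphabet")
  }
  L <- ncol(reference$codes)
  q <- length(reference$alphabet)
  top_k <- .check_count(top_k, "top_k")
  if (is.null(position_sets)) {
    position_sets <- position_sets(L, orders = orders, n_sets = n_sets,
                                   seed = seed)
  } else {
    if (!all(as.character(orders) %in% names(position_sets))) {
      stop("`position_sets` does not cover all requested orders")
    }
    if (!is.null(attr(position_sets, "L")) &&
        attr(position_sets, "L") != L) {
      stop("`position_sets` were drawn for a different L")
    }
  }
  per_set <- list()
  summ <- data.frame(order = integer(), mean_r = numeric(),
                     n_sets = integer(), n_used = integer(),
                     n_skipped = integer())
  allgap_id <- function(n) sum((q - 1) * q^((n - 1L):0L))
  for (n in orders) {
    sets <- position_sets[[as.character(n)]]
    rs <- rep(NA_real_, nrow(sets))
    for (s in seq_len(nrow(sets))) {
      cols <- sets[s, ]
      ref_ids <- .word_ids(reference$codes, cols, q)
      ct <- .count_ids(ref_ids)
      if (exclude_allgap) {
        drop <- ct$values == allgap_id(n)
        ct$values <- ct$values[!drop]
        ct$counts <- ct$counts[!drop]
      }
      if (length(ct$values) == 0L) next
      ord <- order(-ct$counts, ct$values)
      k <- min(top_k, length(ord))
      wids <- ct$values[ord[seq_len(k)]]
      if (metric == "frequency") {
        x <- ct$counts[ord[seq_len(k)]] / length(ref_ids)
        eval_ids <- .word_ids(evaluation$codes, cols, q)
        y <- .freq_of(eval_ids, wids)
      } else {
        words <- t(vapply(wids, .id_to_word, integer(n), n = n, q = q))
        x <- .empirical_cc(reference$codes, cols, words, q)
        y <- .empirical_cc(evaluation$codes, cols, words, q)
      }
      if (length(x) < 2L || anyNA(x) || anyNA(y) ||
          sd(x) == 0 || sd(y) == 0) next
      rs[s] <- cor(x, y)
    }
    used <- sum(!is.na(rs))
    summ <- rbind(summ, data.frame(
      order = n, mean_r = if (used > 0L) mean(rs, na.rm = TRUE) else NA_real_,
      n_sets = nrow(sets), n_used = used, n_skipped = nrow(sets) - used))
    per_set[[as.character(n)]] <- rs
  }
  structure(list(summary = summ, per_set = per_set,
                 metric = if (metric == "frequency") "r20" else "cc_r20",
                 top_k = top_k, seed = seed,
                 position_sets = position_sets),
            class = "r20_result")
}

#' Finite-sampling null r20
#'
#' The r20 obtained when the *training* MSA plays the evaluation role
#' against the reference MSA: the ceiling attainable by a well-specified
#' model whose only error is finite sampling. It decreases with order
#' (smaller word frequencies, larger relative sampling error) and rises
#' with sample size.
#'
#' @param training,reference [encoded_msa] objects.
#' @param ... Passed to [r20()].
#' @return An `"r20_result"`.
#' @export
null_r20 <- function(training, reference, ...) {
  r20(reference = reference, evaluation = training, ...)
}

#' @rdname r20
#' @param ... Passed to [r20()].
#' @export
cc_r20 <- function(reference, evaluation, ...) {
  r20(reference = reference, evaluation = evaluation,
      metric = "connected", ...)
}

#' Bootstrap confidence interval for per-order mean r20
#'
#' Resamples position sets (the retained per-set correlations) with
#' replacement.
#'
#' @param result An `"r20_result"`.
#' @param level Confidence level.
#' @param B Bootstrap replicates.
#' @param seed Integer seed.
#' @return Data frame: order, mean_r, lower, upper.
#' @export
r20_ci <- function(result, level = 0.95, B = 200L, seed = NULL) {
  stopifnot(inherits(result, "r20_result"))
  a <- (1 - level) / 2
  .with_seed(seed, {
    rows <- lapply(names(result$per_set), function(n) {
      rs <- result$per_set[[n]]
      rs <- rs[!is.na(rs)]
      if (length(rs) == 0L) {
        return(data.frame(order = as.integer(n), mean_r = NA_real_,
                          lower = NA_real_, upper = NA_real_))
      }
      bm <- vapply(seq_len(B), function(b) {
        mean(rs[sample.int(length(rs), replace = TRUE)])
      }, numeric(1))
      data.frame(order = as.integer(n), mean_r = mean(rs),
                 lower = unname(quantile(bm, a)),
                 upper = unname(quantile(bm, 1 - a)))
    })
    do.call(rbind, rows)
  })
}

#' @export
print.r20_result <- function(x, ...) {
  cat(sprintf("%s over %d position sets per order (top %d words)\n",
              x$metric, x$summary$n_sets[1L], x$top_k))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
#' @method plot r20_result
plot.r20_result <- function(x, add = FALSE, col = 1, type = "b",
                            ylim = c(0, 1), ...) {
  s <- x$summary
  if (add) {
    graphics::lines(s$order, s$mean_r, col = col, type = type, ...)
  } else {
    graphics::plot(s$order, s$mean_r, col = col, type = type, ylim = ylim,
                   xlab = "word size n", ylab = x$metric, ...)
  }
  invisible(x)
}
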