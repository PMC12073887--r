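#' Amino-acid alphabets for encoded alignments
#'
#' An alphabet is an ordered character vector whose last element is the gap
#' symbol `"-"`. The default protein alphabet holds the 20 canonical amino
#' acids in alphabetical one-letter order followed by the gap, so code `k`
#' always means the same residue across sessions and cached marginals are
#' portable. Reduced alphabets (useful for fast synthetic experiments) take
#' the first `q - 1` canonical residues plus the gap.
#'
#' @param q Number of states including the gap (2 to 21).
#' @return A character vector of class `"msa_alphabet"`; `length(x)` is the
#'   state count `q`, and the gap always has the highest code.
#' @examples
#' aa_alphabet()
#' aa_alphabet(8)
#' @export
aa_alphabet <- function(q = 21L) {
  q <- .check_count(q, "q", min = 2L)
  if (q > 21L) stop("`q` cannot exceed 21 (20 amino acids + gap)")
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  structure(c(aas[seq_len(q - 1L)], "-"), class = "msa_alphabet")
}

#' @export
print.msa_alphabet <- function(x, ...) {
  cat("Alphabet (", length(x), " states, gap last): ",
      paste(unclass(x), collapse = ""), "\n", sep = "")
  invisible(x)
}

# residues treated as unresolvable under the 21-state contract
.ambiguous_residues <- c("B", "Z", "X", "J", "U", "O", "*")

#' Encode aligned character sequences as integer codes
#'
#' Characters are mapped case-insensitively to 1-based codes in alphabet
#' order (gap = `length(alphabet)`). `.` is treated as a gap. Characters
#' outside the alphabet (ambiguity codes B, Z, X, J, U, O, stops) are mapped
#' to the gap under the default policy, with a warning reporting the count;
#' `unknown = "error"` aborts instead.
#'
#' @param seqs Character vector of equal-length aligned sequences.
#' @param ids Sequence identifiers (made unique if duplicated).
#' @param alphabet An [aa_alphabet()].
#' @param unknown Policy for out-of-alphabet characters: `"gap"` or
#'   `"error"`.
#' @return An [encoded_msa] object.
#' @export
encode_msa <- function(seqs, ids = NULL, alphabet = aa_alphabet(),
                       unknown = c("gap", "error")) {
  unknown <- match.arg(unknown)
  if (length(seqs) == 0L) stop("no sequences to encode")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    lab <- if (!is.null(ids)) ids[bad] else paste("record", bad)
    stop(sprintf("ragged alignment: '%s' has length %d, expected %d",
                 lab, lens[bad], lens[1L]))
  }
  q <- length(alphabet)
  chars <- toupper(do.call(rbind, strsplit(seqs, "", fixed = TRUE)))
  codes <- match(chars, unclass(alphabet))
  codes[chars == "."] <- q
  n_unknown <- sum(is.na(codes))
  if (n_unknown > 0L) {
    if (unknown == "error") {
      stop(sprintf("%d character(s) outside the %d-state alphabet", n_unknown, q))
    }
    warning(sprintf("%d out-of-alphabet character(s) mapped to gap", n_unknown))
    codes[is.na(codes)] <- q
  }
  dim(codes) <- dim(chars)
  encoded_msa(codes, ids = ids, alphabet = alphabet)
}

#' Construct an encoded MSA
#'
#' The central alignment container: an `N x L` integer matrix of 1-based
#' alphabet codes (gap = `q`) plus sequence identifiers and the alphabet.
#'
#' @param codes Integer matrix, `N` sequences by `L >= 2` columns, entries
#'   in `1..q`.
#' @param ids Optional identifiers; defaults to `seq_1..seq_N`. Duplicates
#'   are made unique with a warning.
#' @param alphabet An [aa_alphabet()].
#' @return A list of class `"encoded_msa"` with elements `codes`, `ids`,
#'   `alphabet`.
#' @export
encoded_msa <- function(codes, ids = NULL, alphabet = aa_alphabet()) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (nrow(codes) < 1L) stop("an MSA needs at least one sequence")
  if (ncol(codes) < 2L) stop("an MSA needs at least two columns")
  q <- length(alphabet)
  if (anyNA(codes) || any(codes < 1L | codes > q)) {
    stop(sprintf("codes must lie in 1..%d", q))
  }
  if (is.null(ids)) ids <- paste0("seq_", seq_len(nrow(codes)))
  ids <- as.character(ids)
  if (length(ids) != nrow(codes)) stop("length(ids) != number of sequences")
  if (anyDuplicated(ids)) {
    warning("duplicate sequence ids made unique")
    ids <- make.unique(ids)
  }
  dimnames(codes) <- NULL
  structure(list(codes = codes, ids = ids, alphabet = alphabet),
            class = "encoded_msa")
}

#' Decode an encoded MSA back to character sequences
#'
#' @param msa An [encoded_msa].
#' @return Named character vector of aligned sequences.
#' @export
decode_msa <- function(msa) {
  stopifnot(inherits(msa, "encoded_msa"))
  chars <- matrix(unclass(msa$alphabet)[msa$codes], nrow = nrow(msa$codes))
  out <- apply(chars, 1L, paste0, collapse = "")
  names(out) <- msa$ids
  out
}

#' @export
dim.encoded_msa <- function(x) dim(x$codes)

#' @export
print.encoded_msa <- function(x, ...) {
  cat(sprintf("Encoded MSA: %d sequences x %d columns, %d-state alphabet\n",
              nrow(x$codes), ncol(x$codes), length(x$alphabet)))
  n_show <- min(5L, nrow(x$codes))
  shown <- decode_msa(`[.encoded_msa`(x, seq_len(n_show)))
  for (i in seq_len(n_show)) {
    s <- shown[i]
    if (nchar(s) > 60L) s <- paste0(substr(s, 1L, 57L), "...")
    cat(sprintf("  %-15s %s\n", names(shown)[i], s))
  }
  if (nrow(x$codes) > n_show) cat("  ...\n")
  invisible(x)
}

#' @export
`[.encoded_msa` <- function(x, i, ...) {
  encoded_msa(x$codes[i, , drop = FALSE], ids = x$ids[i],
              alphabet = x$alphabet)
}

.same_frame <- function(a, b) {
  ncol(a$codes) == ncol(b$codes) &&
    identical(unclass(a$alphabet), unclass(b$alphabet))
}
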