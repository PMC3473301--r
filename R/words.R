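# Word-frequency features.
#
# For a maximum Markov order K, all words of lengths 1..K+1 are counted by a
# sliding window over the sequence in the alphabet's units (nucleotides,
# codons or amino acids). For the frame-stratified DNA alphabet each word is
# additionally keyed by the codon position (1, 2, 3) of its first base, so
# that the feature dimension equals the interpolated-Markov-model parameter
# budget at the same K.

# lexicographic words of length L over `symbols`, most significant unit first
words_of_length <- function(symbols, L, sep = "") {
  B <- length(symbols)
  code <- 0:(B^L - 1)
  parts <- lapply((L - 1):0, function(o) symbols[(code %/% B^o) %% B + 1L])
  do.call(paste, c(parts, sep = sep))
}

#' Column labels of a word-frequency matrix
#'
#' @param alphabet An [alphabet()] object or name.
#' @param K Maximum Markov order; words of lengths 1..K+1 are labeled.
#' @return Character vector of length [cumulative_parameter_count()].
#'   DNA words carry a \code{posF:} prefix giving the codon position of the
#'   word's first base; codon words join codons with \code{|}.
#' @export
word_labels <- function(alphabet, K) {
  alphabet <- as_alphabet(alphabet)
  sep <- if (alphabet$name == "codon") "|" else ""
  labs <- lapply(seq_len(K + 1L), function(L) {
    w <- words_of_length(alphabet$symbols, L, sep = sep)
    if (alphabet$frame_stratified) {
      as.vector(vapply(1:3, function(f) paste0("pos", f, ":", w),
                       character(length(w))))
    } else {
      w
    }
  })
  unlist(labs, use.names = FALSE)
}

# count vector (length p) for one encoded unit sequence
count_words_units <- function(units, alphabet, K, normalize) {
  B <- alphabet$n_symbols
  n <- length(units)
  blocks <- vector("list", K + 1L)
  codes <- units  # length-1 window codes
  for (L in seq_len(K + 1L)) {
    if (L > 1L)
      codes <- codes[seq_len(n - L + 1L)] * B + units[L:n]
    nw <- n - L + 1L
    if (alphabet$frame_stratified) {
      frame0 <- (seq_len(nw) - 1L) %% 3L          # 0-based frame of first base
      cnt <- tabulate(frame0 * B^L + codes[seq_len(nw)] + 1L, nbins = 3L * B^L)
    } else {
      cnt <- tabulate(codes[seq_len(nw)] + 1L, nbins = B^L)
    }
    if (normalize) cnt <- cnt / nw
    blocks[[L]] <- cnt
  }
  unlist(blocks, use.names = FALSE)
}

#' Count words of lengths 1..K+1 in one preprocessed sequence
#'
#' @param sequence A preprocessed sequence: nucleotides for the dna and codon
#'   alphabets, amino acids for protein.
#' @param alphabet An [alphabet()] object or name.
#' @param K Maximum Markov order (words up to length K+1).
#' @param normalize If TRUE (default) each word length's counts are divided
#'   by the number of windows of that length, giving per-length relative
#'   frequencies; if FALSE raw counts are returned.
#' @param short_sequence Action when the sequence has fewer than K+1 units:
#'   \code{"error"} (default) or \code{"zero"} (long-word counts all zero).
#' @return Named numeric vector of length
#'   \code{cumulative_parameter_count(alphabet, K)}.
#' @export
count_words <- function(sequence, alphabet, K,
                        normalize = TRUE,
                        short_sequence = c("error", "zero")) {
  alphabet <- as_alphabet(alphabet)
  short_sequence <- match.arg(short_sequence)
  units <- encode_units(sequence, alphabet)
  p <- cumulative_parameter_count(alphabet, K)
  if (length(units) < K + 1L) {
    if (short_sequence == "error")
      stop(sprintf("sequence has %d %s unit(s), need at least K+1 = %d",
                   length(units), alphabet$name, K + 1L))
    counts <- count_words_units(units, alphabet,
                                K = max(0L, length(units) - 1L),
                                normalize = normalize)
    counts <- c(counts, numeric(p - length(counts)))
  } else {
    counts <- count_words_units(units, alphabet, K, normalize)
  }
  names(counts) <- word_labels(alphabet, K)
  counts
}

#' Word-frequency predictor matrix for a set of ORFs
#'
#' Builds the n x p matrix X whose rows are per-sequence word frequencies,
#' the predictor of the CPPLS discriminant.
#'
#' @param sequences Character vector of preprocessed sequences (see
#'   [count_words()] for the expected form per alphabet), or an ORF table as
#'   returned by the dataset functions (a data.frame with a \code{seq}
#'   column), in which case row names are taken from its \code{orf_id}.
#' @inheritParams count_words
#' @return Numeric matrix with one row per sequence, column names from
#'   [word_labels()], and attributes \code{alphabet}, \code{K},
#'   \code{normalized}.
#' @export
word_feature_matrix <- function(sequences, alphabet, K,
                                normalize = TRUE,
                                short_sequence = c("error", "zero")) {
  alphabet <- as_alphabet(alphabet)
  short_sequence <- match.arg(short_sequence)
  row_ids <- NULL
  if (is.data.frame(sequences)) {
    row_ids <- sequences$orf_id
    sequences <- sequences$seq
  }
  p <- cumulative_parameter_count(alphabet, K)
  X <- matrix(0, nrow = length(sequences), ncol = p,
              dimnames = list(row_ids, word_labels(alphabet, K)))
  for (i in seq_along(sequences)) {
    units <- encode_units(sequences[i], alphabet)
    if (length(units) < K + 1L) {
      if (short_sequence == "error")
        stop(sprintf("sequence %d has %d %s unit(s), need at least K+1 = %d",
                     i, length(units), alphabet$name, K + 1L))
      cnt <- count_words_units(units, alphabet,
                               K = max(0L, length(units) - 1L),
                               normalize = normalize)
      X[i, seq_along(cnt)] <- cnt
    } else {
      X[i, ] <- count_words_units(units, alphabet, K, normalize)
    }
  }
  attr(X, "alphabet") <- alphabet$name
  attr(X, "K") <- K
  attr(X, "normalized") <- normalize
  X
}

#' Convert ORF nucleotide sequences to a representation's unit strings
#'
#' dna and codon representations keep the nucleotide string; protein
#' translates it with the standard genetic code.
#'
#' @param sequences Character vector of preprocessed (stop-free, in-frame)
#'   nucleotide sequences.
#' @param representation One of \code{"dna"}, \code{"codon"},
#'   \code{"protein"}.
#' @return Character vector of sequences in the representation's units.
#' @export
as_representation <- function(sequences,
                              representation = c("dna", "codon", "protein")) {
  representation <- match.arg(representation)
  if (representation == "protein")
    vapply(sequences, translate_codons, character(1), USE.NAMES = FALSE)
  else
    sequences
}
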