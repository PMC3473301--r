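#' Sequence alphabets for coding-sequence modeling
#'
#' Three representations of a coding sequence are supported:
#' \describe{
#'   \item{dna}{The four nucleotides, stratified by reading frame. Because a
#'     base in codon position 1, 2 or 3 carries different information, the
#'     effective alphabet has \eqn{4 \times 3 = 12} symbols.}
#'   \item{codon}{The 61 sense codons (64 triplets minus the three stop
#'     codons TAA, TAG, TGA).}
#'   \item{protein}{The 20 standard amino acids.}
#' }
#'
#' @param name One of \code{"dna"}, \code{"codon"}, \code{"protein"}.
#' @return An object of class \code{orf_alphabet} with elements
#'   \code{name}, \code{symbols} (ordered character vector),
#'   \code{frame_stratified} (TRUE only for dna) and \code{n_symbols}.
#' @examples
#' alphabet("codon")$n_symbols  # 61
#' @export
alphabet <- function(name = c("dna", "codon", "protein")) {
  name <- match.arg(name)
  symbols <- switch(name,
    dna = DNA_BASES,
    codon = SENSE_CODONS,
    protein = AMINO_ACIDS
  )
  structure(
    list(
      name = name,
      symbols = symbols,
      frame_stratified = identical(name, "dna"),
      n_symbols = length(symbols)
    ),
    class = "orf_alphabet"
  )
}

#' @export
print.orf_alphabet <- function(x, ...) {
  eff <- if (x$frame_stratified) x$n_symbols * 3L else x$n_symbols
  cat(sprintf(
    "<orf_alphabet> %s: %d symbols%s\n", x$name, x$n_symbols,
    if (x$frame_stratified) sprintf(" x 3 frames = %d effective", eff) else ""
  ))
  invisible(x)
}

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

ALL_CODONS <- as.vector(outer(
  outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0
))
ALL_CODONS <- sort(ALL_CODONS)
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

# Standard genetic code (Biostrings::GENETIC_CODE), restricted to sense codons.
AMINO_ACIDS <- sort(unique(unname(
  Biostrings::GENETIC_CODE[setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)]
)))

stopifnot(length(SENSE_CODONS) == 61L, length(AMINO_ACIDS) == 20L)

check_nucleotides <- function(residues) {
  if (length(residues) != 1L || !is.character(residues))
    stop("residues must be a single character string")
  if (grepl("[^ACGT]", residues))
    stop("sequence contains characters other than A/C/G/T ",
         "(ambiguity codes are not supported)")
  invisible(residues)
}

split_codons <- function(residues) {
  n <- nchar(residues)
  if (n %% 3L != 0L) stop("sequence length must be a multiple of 3")
  if (n == 0L) return(character(0))
  substring(residues, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate an in-frame codon sequence to protein
#'
#' Uses the standard genetic code. The input must already be preprocessed:
#' length divisible by 3 and free of in-frame stop codons (see
#' [strip_start_and_stops()]).
#'
#' @param codon_sequence Nucleotide string, length a multiple of 3.
#' @return Amino-acid string with one symbol per codon.
#' @examples
#' translate_codons("AAAGCT")  # "KA"
#' @export
translate_codons <- function(codon_sequence) {
  check_nucleotides(codon_sequence)
  codons <- split_codons(codon_sequence)
  if (any(codons %in% STOP_CODONS))
    stop("in-frame stop codon encountered; apply strip_start_and_stops() first")
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

#' Remove the leading start codon and all in-frame stop codons
#'
#' Both Positives and Negatives are stripped of their endpoints so that
#' classification is driven by sequence content, not by the presence of a
#' proper start or stop: the first codon is dropped if it is a start codon
#' (ATG/GTG/TTG by default) and every in-frame stop codon (TAA/TAG/TGA) is
#' removed. A trailing partial codon is trimmed first. The operation is
#' idempotent.
#'
#' @param residues Nucleotide string.
#' @param start_codons Codons treated as starts at position 1.
#' @return Nucleotide string, length a positive multiple of 3.
#' @examples
#' strip_start_and_stops("ATGGCTTAAGCT")  # "GCTGCT"
#' @export
strip_start_and_stops <- function(residues, start_codons = START_CODONS) {
  check_nucleotides(residues)
  n <- nchar(residues)
  residues <- substr(residues, 1L, n - (n %% 3L))
  codons <- split_codons(residues)
  if (length(codons) > 0L && codons[1L] %in% start_codons)
    codons <- codons[-1L]
  codons <- codons[!(codons %in% STOP_CODONS)]
  if (length(codons) == 0L)
    stop("degenerate sequence: empty after removing start and stop codons")
  paste(codons, collapse = "")
}

#' Number of transition probabilities in an interpolated Markov model
#'
#' Cumulative count over chain orders 0..K: each order-k chain needs
#' \eqn{3 \cdot 4^{k+1}} probabilities for the frame-stratified DNA alphabet,
#' \eqn{20^{k+1}} for protein and \eqn{61^{k+1}} for codon. This also equals
#' the number of word-frequency features of lengths 1..K+1 used by the CPPLS
#' predictor matrix, which is what makes the two methods comparable at equal
#' K.
#'
#' @param alphabet An [alphabet()] object or its name.
#' @param K Maximum chain order (integer >= 0).
#' @return A numeric count (exact as a double well beyond 2^31).
#' @examples
#' cumulative_parameter_count("dna", 4)    # 4092
#' cumulative_parameter_count("codon", 1)  # 3782
#' @export
cumulative_parameter_count <- function(alphabet, K) {
  alphabet <- as_alphabet(alphabet)
  if (K < 0 || K != round(K)) stop("K must be a non-negative integer")
  k <- 0:K
  per_order <- if (alphabet$frame_stratified) {
    3 * 4^(k + 1)
  } else {
    alphabet$n_symbols^(k + 1)
  }
  sum(per_order)
}

as_alphabet <- function(x) {
  if (inherits(x, "orf_alphabet")) return(x)
  if (is.character(x) && length(x) == 1L) return(alphabet(x))
  stop("unknown alphabet")
}

#' Default maximum chain order per representation
#'
#' Orders giving comparable parameter budgets across representations
#' (about 4000--8500 probabilities): 4 for frame-stratified DNA, 2 for
#' protein, 1 for codon.
#'
#' @param name Alphabet name.
#' @return Integer order.
#' @export
default_order <- function(name = c("dna", "codon", "protein")) {
  switch(match.arg(name), dna = 4L, codon = 1L, protein = 2L)
}

# Encode one preprocessed sequence as 0-based integer units of its alphabet.
# dna: one unit per nucleotide; codon: one unit per codon (input nucleotide
# string); protein: one unit per amino acid (input protein string).
encode_units <- function(sequence, alphabet) {
  alphabet <- as_alphabet(alphabet)
  units <- switch(alphabet$name,
    dna = strsplit(sequence, "", fixed = TRUE)[[1L]],
    codon = split_codons(sequence),
    protein = strsplit(sequence, "", fixed = TRUE)[[1L]]
  )
  idx <- match(units, alphabet$symbols)
  if (anyNA(idx)) {
    bad <- unique(units[is.na(idx)])
    stop(sprintf("symbol(s) not in %s alphabet: %s", alphabet$name,
                 paste(bad, collapse = ", ")))
  }
  idx - 1L
}
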