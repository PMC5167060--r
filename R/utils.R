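#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Enumerate all k-mers of a sequence
#'
#' @param seq a single DNA string.
#' @param k k-mer length.
#' @return character vector of substrings of length `k` (empty when the
#'   sequence is shorter than `k`).
#' @export
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

#' Translate DNA to amino acids
#'
#' Standard genetic code; the input length must be a multiple of 3.
#' Codons containing characters outside A/C/G/T translate to `X`.
#'
#' @param seq a single DNA string.
#' @return a single amino-acid string (`*` for stop codons).
#' @export
translate_dna <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return("")
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3")
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Phred+33 decoding / encoding
qual_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

int_to_qual <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

reverse_string <- function(x) {
  vapply(strsplit(x, NULL), function(ch) paste(rev(ch), collapse = ""), character(1))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return named character vector, sequences upper-cased.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}
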