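#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   BStringSet PhredQuality pairwiseAlignment nmatch
#'   nucleotideSubstitutionMatrix reverseComplement
#' @importFrom IRanges IRanges coverage reduce width
#' @importFrom S4Vectors mcols
#' @importFrom stats rbinom rlnorm rnorm runif setNames
#' @importFrom utils head read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a character vector of DNA sequences
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that keeps plain
#' character vectors as input and output.
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of sequences; names are the full header
#'   lines (without `>`).
#' @export
read_fasta <- function(path) {
  x <- readDNAStringSet(path, format = "fasta")
  setNames(as.character(x), names(x))
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  writeXStringSet(DNAStringSet(seqs), path, format = "fasta", width = 70L)
  invisible(path)
}

## integer rounding, ties away from zero (Table-style "half up")
round_half_up <- function(x) {
  floor(x + 0.5)
}

## deterministic per-stage seed derived from the master seed; keeps stages
## decoupled so regenerating reads does not disturb the transcript draw
stage_seed <- function(seed, stage) {
  offsets <- c(truth = 101L, assemblies = 211L, reads = 307L,
               alignments = 401L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a
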