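#' Amino-acid composition (AAC)
#'
#' Frequency of each of the 20 standard amino acids, normalized by sequence
#' length, indexed alphabetically A..Y. Entries are nonnegative and sum to 1.
#'
#' @param sequence A single nonempty string over the 20 standard codes.
#' @return Named numeric vector of length 20.
#' @examples
#' aac("ACDC")
#' @export
aac <- function(sequence) {
  res <- sequence_residues(sequence)
  counts <- table(factor(res, levels = AMINO_ACIDS))
  stats::setNames(as.numeric(counts) / length(res), AMINO_ACIDS)
}

#' Dipeptide composition (DPC)
#'
#' Frequency of each of the 400 ordered amino-acid pairs among the N - 1
#' overlapping adjacent dipeptides, indexed first-letter major (AA, AC, AD,
#' ..., YY). Entries are nonnegative and sum to 1. Unlike AAC, DPC is
#' sensitive to residue order.
#'
#' @param sequence A single string over the 20 standard codes, length >= 2.
#' @return Named numeric vector of length 400.
#' @examples
#' dpc("ACDC")[c("AC", "CD", "DC")]
#' @export
dpc <- function(sequence) {
  res <- sequence_residues(sequence)
  n <- length(res)
  if (n < 2L) abort("dipeptide composition requires sequence length >= 2")
  pairs <- paste0(res[-n], res[-1L])
  counts <- table(factor(pairs, levels = DIPEPTIDES))
  stats::setNames(as.numeric(counts) / (n - 1L), DIPEPTIDES)
}
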