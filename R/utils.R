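# Small internal helpers shared across modules.

#' Permitted uORF start codons
#'
#' The canonical ATG start plus the nine near-cognate codons (single-base
#' variants of ATG) that support translation initiation.
#'
#' @return Character vector of ten 3-mers, ATG first.
#' @export
#' @examples
#' startCodonSet()
startCodonSet <- function() {
  c("ATG", "TTG", "GTG", "CTG", "AAG", "AGG", "ACG", "ATA", "ATT", "ATC")
}

stopCodons <- function() c("TAA", "TAG", "TGA")

# reverse complement for plain character vectors; N maps to N
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complementBase <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

# all overlapping 3-mers of a sequence (positions 1..n-2)
threemers <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(character(0))
  substring(seq, seq_len(n - 2L), seq_len(n - 2L) + 2L)
}

# binary entropy (base 2) from a count vector; 0 log 0 := 0
entropy2 <- function(counts) {
  n <- sum(counts)
  if (n == 0L) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# percentage rounded to one decimal, as printed in study summaries
pct1 <- function(num, den) round(100 * num / den, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
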