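# Fixture builders and independent oracles used across the suite.

makeGenome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

randomNt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a random single-exon coding transcript (plus its genome) with the given
# 5'UTR length; CDS is built codon-wise with no internal in-frame stop
randomCodingTx <- function(utrLen, nCodons = 30, id = "tx1", strand = "+") {
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  cds <- paste0("ATG", paste(sample(sense, nCodons, replace = TRUE),
                             collapse = ""), sample(c("TAA","TAG","TGA"), 1))
  txSeq <- paste0(randomNt(utrLen), cds, randomNt(30))
  genome <- makeGenome(c(chrT = if (strand == "+") txSeq
                         else as.character(Biostrings::reverseComplement(
                           Biostrings::DNAString(txSeq)))))
  tx <- transcriptModel(id, "g1", "chrT", strand, 1L, nchar(txSeq),
                        cdsStart = utrLen + 1L,
                        cdsEnd = utrLen + nchar(cds))
  list(tx = tx, genome = genome, seq = txSeq)
}

# Independent brute-force uORF enumerator: tests every start position and
# walks codon by codon to the first in-frame stop. No shared code with
# scanTranscript's findInterval machinery.
bruteForceScan <- function(seq, cdsStart, cdsEnd, starts = startCodonSet()) {
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (p in seq_len(max(0L, cdsStart - 3L))) {
    if (!substr(seq, p, p + 2L) %in% starts) next
    q <- p + 3L
    while (q + 2L <= nchar(seq)) {
      if (substr(seq, q, q + 2L) %in% stops) {
        if (q + 2L <= cdsEnd)
          out[[length(out) + 1L]] <- data.frame(
            startTx = p, stopTx = q, codon = substr(seq, p, p + 2L),
            stringsAsFactors = FALSE)
        break  # first in-frame stop terminates the reading frame
      }
      q <- q + 3L
    }
  }
  if (!length(out)) return(data.frame(startTx = integer(0),
                                      stopTx = integer(0),
                                      codon = character(0)))
  do.call(rbind, out)
}

# Naive recursive MDLP oracle: every midpoint between adjacent distinct
# values is evaluated with table()-based entropies; the Fayyad-Irani MDL
# criterion decides acceptance. Independent arithmetic from mdlpDiscretize.
mdlpOracle <- function(x, y) {
  y <- as.logical(y)
  keep <- !is.na(x)
  x <- x[keep]; y <- y[keep]
  ent <- function(lab) {
    if (!length(lab)) return(0)
    p <- table(lab) / length(lab)
    -sum(ifelse(p > 0, p * log2(p), 0))
  }
  split1 <- function(x, y) {
    ord <- order(x); x <- x[ord]; y <- y[ord]
    n <- length(x)
    if (n < 2L) return(NULL)
    cutCands <- unique((x[-n] + x[-1])[x[-n] != x[-1]] / 2)
    if (!length(cutCands)) return(NULL)
    best <- NULL
    for (cut in sort(cutCands)) {
      l <- y[x < cut]; r <- y[x >= cut]
      gain <- ent(y) - (length(l) * ent(l) + length(r) * ent(r)) / n
      if (is.null(best) || gain > best$gain + 1e-12)
        best <- list(cut = cut, gain = gain, l = l, r = r)
    }
    k <- length(unique(y)); k1 <- length(unique(best$l))
    k2 <- length(unique(best$r))
    delta <- log2(3^k - 2) - (k * ent(y) - k1 * ent(best$l) - k2 * ent(best$r))
    if (best$gain <= (log2(n - 1) + delta) / n) return(NULL)
    best$cut
  }
  recurse <- function(x, y) {
    cut <- split1(x, y)
    if (is.null(cut)) return(numeric(0))
    c(recurse(x[x < cut], y[x < cut]), cut, recurse(x[x >= cut], y[x >= cut]))
  }
  sort(recurse(x, y))
}

# small, fast simulation config for tests that do not need the full scale
smallConfig <- function(seed = 1, ...) {
  simulationConfig(seed = seed, nTranscripts = 40L, nLnc = 4L,
                   nLiterature = 3L, nPeptides = 5L,
                   nGainVariants = 8L, nLossVariants = 20L, ...)
}
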