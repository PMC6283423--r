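# Reading and validating the study inputs: genome FASTA, GTF annotation,
# TIS call tables, conservation/expression tracks, literature and aTIS
# position lists, and VCF variants. Spliced sequences and coordinate maps
# live here too.

#' Load a genome FASTA
#'
#' Sequences are uppercased on load (soft-masked lowercase bases would
#' otherwise defeat case-sensitive codon matching) and the alphabet is
#' restricted to A/C/G/T/N.
#'
#' @param file path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] (one entry per contig).
#' @export
loadGenome <- function(file) {
  # read as raw strings first: DNA parsing would silently drop characters
  # outside the DNA alphabet instead of flagging them
  x <- Biostrings::readBStringSet(file)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) stop("duplicate contig names in ", file)
  chars <- toupper(as.character(x))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad))
    stop("non-ACGTN characters in contig(s): ",
         paste(names(x)[bad], collapse = ", "))
  Biostrings::DNAStringSet(chars)
}

#' Load transcript models from a GTF annotation
#'
#' Reads a minimal GTF dialect: `exon` and `CDS` features carrying
#' `transcript_id` and `gene_id` attributes (and optionally
#' `transcript_biotype`). GTF coordinates are 1-based inclusive; CDS records
#' are taken to include the stop codon. Transcripts violating the model
#' invariants -- CDS length not divisible by 3, or not ending in a stop
#' codon -- are dropped with a logged reason rather than aborting the load.
#' Unsorted exons are repaired by sorting.
#'
#' @param gtfFile path to the GTF file.
#' @param genome genome as returned by [loadGenome()]; used to verify
#'   contigs and CDS stop codons.
#' @return A list with elements `transcripts` (list of
#'   [TranscriptModel-class]) and `dropped` (data.frame of `txId`,
#'   `reason`).
#' @export
loadAnnotation <- function(gtfFile, genome) {
  gr <- rtracklayer::import(gtfFile, format = "gtf")
  df <- as.data.frame(gr)
  keep <- df$type %in% c("exon", "CDS")
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) stop("no exon/CDS records in ", gtfFile)
  missingContig <- setdiff(unique(as.character(df$seqnames)), names(genome))
  if (length(missingContig))
    stop("annotation references contig(s) absent from genome: ",
         paste(missingContig, collapse = ", "))

  transcripts <- list()
  dropped <- data.frame(txId = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  dropTx <- function(id, why) {
    dropped[nrow(dropped) + 1L, ] <<- list(id, why)
  }

  for (id in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == id, , drop = FALSE]
    ex <- sub[sub$type == "exon", , drop = FALSE]
    if (!nrow(ex)) { dropTx(id, "no exon records"); next }
    strand <- as.character(ex$strand[1])
    contig <- as.character(ex$seqnames[1])
    geneId <- as.character(ex$gene_id[1])
    ord <- order(ex$start, decreasing = (strand == "-"))
    ex <- ex[ord, , drop = FALSE]
    biotype <- if ("transcript_biotype" %in% names(sub) &&
                   !is.na(sub$transcript_biotype[1]))
      sub$transcript_biotype[1] else NA_character_

    cds <- sub[sub$type == "CDS", , drop = FALSE]
    cdsStart <- cdsEnd <- NA_integer_
    if (nrow(cds)) {
      gmin <- min(cds$start); gmax <- max(cds$end)
      tx0 <- transcriptModel(id, geneId, contig, strand, ex$start, ex$end)
      p1 <- genomeToTranscript(tx0, gmin)
      p2 <- genomeToTranscript(tx0, gmax)
      if (is.na(p1) || is.na(p2)) { dropTx(id, "CDS outside exons"); next }
      cdsStart <- min(p1, p2); cdsEnd <- max(p1, p2)
      if ((cdsEnd - cdsStart + 1L) %% 3L != 0L) {
        dropTx(id, "CDS length not divisible by 3"); next
      }
    }
    bt <- if (!is.na(biotype)) {
      if (biotype %in% c("protein_coding", "coding")) "coding" else "lncRNA"
    } else if (is.na(cdsStart)) "lncRNA" else "coding"
    tx <- transcriptModel(id, geneId, contig, strand, ex$start, ex$end,
                          cdsStart, cdsEnd, biotype = bt)
    if (!is.na(cdsStart)) {
      seq <- splicedSequence(tx, genome)
      stop3 <- substr(seq, cdsEnd - 2L, cdsEnd)
      if (!stop3 %in% stopCodons()) {
        dropTx(id, "CDS does not end with a stop codon"); next
      }
    }
    transcripts[[id]] <- tx
  }
  list(transcripts = transcripts, dropped = dropped)
}

#' Spliced transcript sequence
#'
#' Concatenates exon sequences 5'->3' in transcript orientation;
#' minus-strand exons are reverse-complemented.
#'
#' @param tx a [TranscriptModel-class].
#' @param genome genome [Biostrings::DNAStringSet].
#' @return Character scalar, the spliced sequence.
#' @export
splicedSequence <- function(tx, genome) {
  if (!tx@contig %in% names(genome))
    stop("contig '", tx@contig, "' not in genome")
  clen <- Biostrings::width(genome)[match(tx@contig, names(genome))]
  if (any(tx@exonEnds > clen) || any(tx@exonStarts < 1L))
    stop("exon outside contig bounds for transcript ", tx@txId)
  full <- as.character(genome[[tx@contig]])
  parts <- substring(full, pmin(tx@exonStarts, tx@exonEnds),
                     pmax(tx@exonStarts, tx@exonEnds))
  if (tx@strand == "-") parts <- revComp(parts)
  paste(parts, collapse = "")
}

#' Map transcript positions to genomic positions
#'
#' Strand-aware inverse of [genomeToTranscript()]. Vectorized over `pos`.
#'
#' @param tx a [TranscriptModel-class].
#' @param pos transcript positions (1-based).
#' @return Integer vector of genomic positions on `tx@contig`.
#' @export
transcriptToGenome <- function(tx, pos) {
  widths <- tx@exonEnds - tx@exonStarts + 1L
  cum <- cumsum(widths)
  L <- cum[length(cum)]
  if (any(pos < 1L | pos > L))
    stop("position out of range [1,", L, "] for transcript ", tx@txId, ": ",
         paste(pos[pos < 1L | pos > L], collapse = ","))
  i <- findInterval(pos - 0.5, c(0L, cum))
  off <- pos - c(0L, cum)[i]
  if (tx@strand == "+") tx@exonStarts[i] + off - 1L
  else tx@exonEnds[i] - off + 1L
}

#' Map a genomic position into transcript coordinates
#'
#' @param tx a [TranscriptModel-class].
#' @param gpos genomic positions on the transcript's contig (vectorized).
#' @return Integer transcript positions; `NA` for intronic/outside positions.
#' @export
genomeToTranscript <- function(tx, gpos) {
  widths <- tx@exonEnds - tx@exonStarts + 1L
  cumBefore <- c(0L, cumsum(widths))[seq_along(widths)]
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_along(widths)) {
    lo <- min(tx@exonStarts[i], tx@exonEnds[i])
    hi <- max(tx@exonStarts[i], tx@exonEnds[i])
    hit <- !is.na(gpos) & gpos >= lo & gpos <= hi
    if (any(hit)) {
      off <- if (tx@strand == "+") gpos[hit] - tx@exonStarts[i] + 1L
             else tx@exonEnds[i] - gpos[hit] + 1L
      out[hit] <- cumBefore[i] + off
    }
  }
  out
}

#' Read a translation-initiation-site call table
#'
#' BED-like TSV with columns `contig`, `start` (0-based position of the
#' start-codon first base, converted to 1-based on read), `strand`, `reads`.
#'
#' @param file path to the TSV.
#' @param experiment experiment identifier attached to the calls.
#' @return data.frame with columns `contig`, `pos` (1-based), `strand`,
#'   `reads`, `experiment`.
#' @export
readTisCalls <- function(file, experiment) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("contig", "start", "strand", "reads")
  if (!all(need %in% names(df)))
    stop("TIS table must have columns: ", paste(need, collapse = ", "))
  if (any(df$reads < 0)) stop("negative read count in ", file)
  data.frame(contig = as.character(df$contig), pos = df$start + 1L,
             strand = df$strand, reads = df$reads,
             experiment = experiment, stringsAsFactors = FALSE)
}

#' Read a per-base conservation track (bedGraph)
#'
#' Expands the track into one numeric vector per contig (unscored bases get
#' `NA`). Suited to the mini-genome scale this package targets; a full
#' genome would need an interval representation instead.
#'
#' @param file bedGraph path.
#' @param genome genome [Biostrings::DNAStringSet] (defines contig lengths).
#' @return Named list of numeric vectors, one per contig.
#' @export
loadConservation <- function(file, genome) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  out <- lapply(Biostrings::width(genome), function(w) rep(NA_real_, w))
  names(out) <- names(genome)
  df <- as.data.frame(gr)
  for (ctg in intersect(unique(as.character(df$seqnames)), names(out))) {
    sub <- df[df$seqnames == ctg, , drop = FALSE]
    for (j in seq_len(nrow(sub)))
      out[[ctg]][sub$start[j]:sub$end[j]] <- sub$score[j]
  }
  out
}

#' Read a transcript expression table
#'
#' @param file TSV with columns `txId`, `expression`.
#' @return data.frame with those columns.
#' @export
readExpression <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("txId", "expression") %in% names(df)))
    stop("expression table must have columns txId, expression")
  df
}

#' Read a literature-positive uORF list
#'
#' @param file TSV with columns `gene`, `contig`, `pos` (1-based genomic
#'   position of the start-codon first base), `strand`.
#' @return data.frame with those columns (zero rows if the file is empty).
#' @export
readLiterature <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("gene", "contig", "pos", "strand")
  if (!all(need %in% names(df)))
    stop("literature table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read an aTIS (alternative translation initiation site) position list
#'
#' @param file TSV with columns `contig`, `pos` (1-based), `strand`.
#' @return data.frame with those columns.
#' @export
readAtis <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "strand")
  if (!all(need %in% names(df)))
    stop("aTIS table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read variants from a VCF
#'
#' Parses CHROM/POS/ID/REF/ALT via \pkg{vcfR}. Multi-allelic records are
#' expanded to one row per alternate allele.
#'
#' @param file VCF path (v4.x, plain or gzipped).
#' @return data.frame with columns `id`, `contig`, `pos`, `ref`, `alt`,
#'   `isSnv`.
#' @export
readVariants <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    data.frame(id = if (is.na(fix$ID[i])) sprintf("var%d", i) else fix$ID[i],
               contig = fix$CHROM[i], pos = as.integer(fix$POS[i]),
               ref = fix$REF[i], alt = alts, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$isSnv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    df$alt %in% c("A", "C", "G", "T")
  df
}
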