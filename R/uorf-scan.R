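# Genome-wide uORF enumeration. A uORF is a start codon (ATG or
# near-cognate) whose first base lies fully within the 5'UTR and whose
# first in-frame stop codon ends at or before the end of the CDS. All three
# reading frames are examined; candidates whose first in-frame stop falls
# beyond the CDS end are discarded entirely (a later stop is unreachable by
# a terminating ribosome).

# Core ORF enumerator on a spliced sequence.
#   startMax: largest allowed position for the start-codon first base
#   stopMax:  largest allowed position for the stop-codon third base
# Returns data.frame(startTx, stopTx, codon); stopTx = stop-codon first base.
enumerateOrfs <- function(seq, starts, startMax, stopMax) {
  tm <- threemers(seq)
  if (!length(tm) || startMax < 1L)
    return(data.frame(startTx = integer(0), stopTx = integer(0),
                      codon = character(0), stringsAsFactors = FALSE))
  cand <- which(tm %in% starts)
  cand <- cand[cand <= startMax]
  stopPos <- which(tm %in% stopCodons())
  out <- vector("list", 3L)
  for (r in 0:2) {
    cr <- cand[cand %% 3L == r]
    if (!length(cr)) next
    sr <- stopPos[stopPos %% 3L == r]
    idx <- findInterval(cr + 2L, sr) + 1L  # first in-frame stop at >= p+3
    q <- ifelse(idx <= length(sr), sr[idx], NA_integer_)
    ok <- !is.na(q) & (q + 2L) <= stopMax
    if (any(ok))
      out[[r + 1L]] <- data.frame(startTx = cr[ok], stopTx = q[ok],
                                  codon = tm[cr[ok]], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    return(data.frame(startTx = integer(0), stopTx = integer(0),
                      codon = character(0), stringsAsFactors = FALSE))
  res[order(res$startTx), , drop = FALSE]
}

#' Topology of a uORF relative to the CDS
#'
#' `upstream` if the stop codon ends before the CDS start; otherwise
#' `shared_stop_extension` if the uORF is in frame with the CDS and uses the
#' CDS stop codon (an N-terminal extension of the main protein); otherwise
#' `cds_overlap` (out-of-frame overlap).
#'
#' @param startTx,stopTx start-codon and stop-codon first-base transcript
#'   positions (vectorized).
#' @param cdsStart,cdsEnd CDS boundaries in transcript coordinates.
#' @return Character vector of topology labels.
#' @export
classifyTopology <- function(startTx, stopTx, cdsStart, cdsEnd) {
  stopEnd <- stopTx + 2L
  frame <- (startTx - cdsStart) %% 3L
  ifelse(stopEnd < cdsStart, "upstream",
         ifelse(frame == 0L & stopEnd == cdsEnd, "shared_stop_extension",
                "cds_overlap"))
}

#' Scan one transcript for candidate uORFs
#'
#' Every position `1..(cdsStart - 3)` whose 3-mer is in the start-codon set
#' and whose first in-frame stop codon ends at or before the CDS end yields
#' exactly one record. Transcripts with a 5'UTR shorter than 3 nt (or
#' non-coding transcripts) yield an empty set.
#'
#' @param tx a coding [TranscriptModel-class].
#' @param seq its spliced sequence (from [splicedSequence()]).
#' @param starts permitted start codons, default [startCodonSet()].
#' @return data.frame of catalog records (see [UorfCatalog-class]).
#' @export
#' @examples
#' tx <- transcriptModel("tx1", "g1", "c1", "+", 1L, 19L,
#'                       cdsStart = 11L, cdsEnd = 19L)
#' scanTranscript(tx, "ATGAAATAGCATGGATTAA")
scanTranscript <- function(tx, seq, starts = startCodonSet()) {
  empty <- data.frame(key = character(0), contig = character(0),
                      strand = character(0), gStart = integer(0),
                      gStop = integer(0), txId = character(0),
                      startTx = integer(0), stopTx = integer(0),
                      length = integer(0), codon = character(0),
                      topology = character(0), frame = integer(0),
                      stringsAsFactors = FALSE)
  if (is.na(tx@cdsStart) || tx@cdsStart < 4L) return(empty)
  orfs <- enumerateOrfs(seq, starts, startMax = tx@cdsStart - 3L,
                        stopMax = tx@cdsEnd)
  if (!nrow(orfs)) return(empty)
  gStart <- transcriptToGenome(tx, orfs$startTx)
  gStop <- transcriptToGenome(tx, orfs$stopTx + 2L)
  topo <- classifyTopology(orfs$startTx, orfs$stopTx, tx@cdsStart, tx@cdsEnd)
  key <- uorfKey(tx, orfs$startTx, orfs$stopTx + 2L, gStart, gStop)
  data.frame(key = key, contig = tx@contig, strand = tx@strand,
             gStart = gStart, gStop = gStop, txId = tx@txId,
             startTx = orfs$startTx, stopTx = orfs$stopTx,
             length = orfs$stopTx + 2L - orfs$startTx + 1L,
             codon = orfs$codon, topology = topo,
             frame = (orfs$startTx - tx@cdsStart) %% 3L,
             stringsAsFactors = FALSE)
}

# Genomic-coordinate identity of a uORF. Endpoints alone are ambiguous for
# spliced UTRs, so exon-junction genomic positions falling inside the uORF
# span are appended as a chain.
uorfKey <- function(tx, startTx, endTx, gStart, gStop) {
  cum <- cumsum(tx@exonEnds - tx@exonStarts + 1L)
  junctions <- cum[-length(cum)]
  chain <- vapply(seq_along(startTx), function(i) {
    j <- junctions[junctions >= startTx[i] & junctions < endTx[i]]
    if (!length(j)) "" else paste(transcriptToGenome(tx, j), collapse = "|")
  }, character(1))
  paste(tx@contig, tx@strand, gStart, gStop, chain, sep = ":")
}

#' Scan a transcript set for uORFs
#'
#' Runs [scanTranscript()] over all coding transcripts, then (optionally)
#' removes N-terminal extensions and aTIS-coincident starts
#' ([applyCleansing()]) and collapses records sharing a genomic key
#' ([deduplicateUorfs()]).
#'
#' @param transcripts list of [TranscriptModel-class] (e.g. from
#'   [loadAnnotation()]`$transcripts`).
#' @param genome genome [Biostrings::DNAStringSet].
#' @param starts permitted start codons.
#' @param atis optional aTIS data.frame (`contig`, `pos`, `strand`).
#' @param cleanse,dedup logical switches for the two post-processing steps.
#' @return A [UorfCatalog-class].
#' @export
scanUorfs <- function(transcripts, genome, starts = startCodonSet(),
                      atis = NULL, cleanse = TRUE, dedup = TRUE) {
  parts <- lapply(transcripts, function(tx) {
    if (is.na(tx@cdsStart)) return(NULL)
    scanTranscript(tx, splicedSequence(tx, genome), starts)
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  rec <- if (length(parts)) do.call(rbind, parts) else scanTranscript(
    transcriptModel("x", "x", names(genome)[1], "+", 1L, 3L, 1L, 3L),
    "NNN")
  cat <- UorfCatalog(rec, stats = list(nScanned = nrow(rec)))
  if (cleanse) cat <- applyCleansing(cat, atis)
  if (dedup) cat <- deduplicateUorfs(cat)
  cat
}

#' Remove N-terminal extensions and aTIS-coincident uORFs
#'
#' Shared-stop-codon uORFs act as 5' extensions of the main protein and may
#' retain its function; uORFs starting at an annotated alternative
#' translation initiation site of the CDS likewise. Both classes are
#' removed, with counts recorded in the catalog stats.
#'
#' @param catalog a [UorfCatalog-class].
#' @param atis optional data.frame (`contig`, `pos`, `strand`) of aTIS
#'   genomic positions.
#' @return Filtered [UorfCatalog-class].
#' @export
applyCleansing <- function(catalog, atis = NULL) {
  rec <- catalog@records
  ext <- rec$topology == "shared_stop_extension"
  nAtis <- 0L
  atisHit <- rep(FALSE, nrow(rec))
  if (!is.null(atis) && nrow(atis)) {
    akey <- paste(atis$contig, atis$strand, atis$pos, sep = ":")
    atisHit <- paste(rec$contig, rec$strand, rec$gStart, sep = ":") %in% akey
    nAtis <- sum(atisHit & !ext)
  }
  keep <- !(ext | atisHit)
  stats <- catalog@stats
  stats$nExtensionsRemoved <- sum(ext)
  stats$nAtisRemoved <- nAtis
  UorfCatalog(rec[keep, , drop = FALSE], stats)
}

#' Collapse uORFs shared across transcripts to unique genomic keys
#'
#' A single uORF present on multiple transcript isoforms is counted once;
#' the lexicographically smallest transcript id becomes its representative.
#'
#' @param catalog a [UorfCatalog-class].
#' @return Deduplicated [UorfCatalog-class]; `stats$nCollapsed` counts the
#'   removed duplicates.
#' @export
deduplicateUorfs <- function(catalog) {
  rec <- catalog@records
  ord <- order(rec$key, rec$txId)
  rec <- rec[ord, , drop = FALSE]
  keep <- !duplicated(rec$key)
  stats <- catalog@stats
  stats$nCollapsed <- sum(!keep)
  UorfCatalog(rec[keep, , drop = FALSE], stats)
}

#' Catalog records as genomic ranges
#'
#' One range per uORF spanning the start-codon first base to the stop-codon
#' third base (genomic span; introns are not excised). Useful for browser
#' export via \pkg{rtracklayer}.
#'
#' @param catalog a [UorfCatalog-class].
#' @return A [GenomicRanges::GRanges] with catalog metadata columns.
#' @export
uorfRanges <- function(catalog) {
  rec <- catalog@records
  GenomicRanges::GRanges(
    seqnames = rec$contig,
    ranges = IRanges::IRanges(pmin(rec$gStart, rec$gStop),
                              pmax(rec$gStart, rec$gStop)),
    strand = rec$strand,
    key = rec$key, txId = rec$txId, codon = rec$codon,
    topology = rec$topology, frame = rec$frame)
}

#' Write a uORF catalog to TSV
#'
#' @param catalog a [UorfCatalog-class] (or a labeled catalog data.frame).
#' @param file output path.
#' @export
writeCatalog <- function(catalog, file) {
  rec <- if (is(catalog, "UorfCatalog")) catalog@records else catalog
  utils::write.table(rec, file, sep = "\t", quote = FALSE, row.names = FALSE)
}
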