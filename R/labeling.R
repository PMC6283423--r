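# Intersecting the scanned catalog with per-experiment TIS calls and
# literature positives to produce the 2-voted / 1-voted / unlabeled
# partition, translated-lncRNA-ORF calls, and the ribosome-binding-strength
# stratification.

# TIS call lookup: TRUE where (contig, strand, gStart) has a call within
# +/- window nt. Returns the summed reads in the window as an attribute.
tisMatch <- function(contig, strand, gStart, tis, window = 1L) {
  readSum <- numeric(length(gStart))
  hit <- rep(FALSE, length(gStart))
  callKey <- paste(tis$contig, tis$strand, tis$pos, sep = ":")
  reads <- tapply(tis$reads, callKey, sum)
  for (d in -window:window) {
    k <- paste(contig, strand, gStart + d, sep = ":")
    m <- match(k, names(reads))
    found <- !is.na(m)
    hit <- hit | found
    readSum[found] <- readSum[found] + reads[m[found]]
  }
  attr(hit, "reads") <- readSum
  hit
}

#' Assign experiment votes and partition the catalog
#'
#' A uORF is detected by an experiment iff a TIS call from that experiment
#' lies within `window` nt of the uORF start-codon first base, on the same
#' strand. Literature positives contribute one additional vote source (or
#' promote straight to 2-voted when `literatureTwoVoted = TRUE`). The
#' partition is exhaustive and exclusive: votes >= 2 -> `two_voted`,
#' votes == 1 -> `one_voted`, otherwise `unlabeled`.
#'
#' @param catalog a [UorfCatalog-class].
#' @param tisSets named list of TIS call data.frames (see [readTisCalls()]).
#' @param literature optional data.frame from [readLiterature()].
#' @param window matching half-window in nt (default 1).
#' @param literatureTwoVoted if `TRUE`, any literature positive is placed in
#'   the 2-voted set regardless of profiling votes.
#' @return data.frame: the catalog records plus one `detected.<experiment>`
#'   and `reads.<experiment>` column pair per experiment, `literature`,
#'   `votes` and `partition` columns.
#' @export
assignVotes <- function(catalog, tisSets, literature = NULL, window = 1L,
                        literatureTwoVoted = FALSE) {
  rec <- uorfRecords(catalog)
  if (is.null(names(tisSets)))
    names(tisSets) <- vapply(tisSets, function(t) t$experiment[1], character(1))
  det <- matrix(FALSE, nrow(rec), length(tisSets),
                dimnames = list(NULL, names(tisSets)))
  for (e in names(tisSets)) {
    hit <- tisMatch(rec$contig, rec$strand, rec$gStart, tisSets[[e]], window)
    det[, e] <- hit
    rec[[paste0("reads.", e)]] <- attr(hit, "reads")
    if (nrow(tisSets[[e]]) > 0L && nrow(rec) > 0L && !any(hit))
      warning("experiment '", e, "' has calls but zero catalog ",
              "intersections; assembly mismatch?")
  }
  for (e in names(tisSets)) rec[[paste0("detected.", e)]] <- det[, e]
  lit <- rep(FALSE, nrow(rec))
  if (!is.null(literature) && nrow(literature)) {
    lkey <- paste(literature$contig, literature$strand, literature$pos,
                  sep = ":")
    lit <- paste(rec$contig, rec$strand, rec$gStart, sep = ":") %in% lkey
  }
  rec$literature <- lit
  votes <- rowSums(det) + as.integer(lit)
  if (literatureTwoVoted) votes[lit] <- pmax(votes[lit], 2L)
  rec$votes <- as.integer(votes)
  rec$partition <- ifelse(votes >= 2, "two_voted",
                          ifelse(votes == 1, "one_voted", "unlabeled"))
  rec
}

#' Call translated ORFs on lncRNA transcripts
#'
#' Enumerates ORFs (start codon with an in-frame stop on the transcript)
#' on non-coding transcripts and flags an ORF as translated in an
#' experiment iff the summed TIS reads within `window` nt of its start
#' reach `minReads` (default 10). ORFs translated in at least two
#' experiments are 2-voted positives.
#'
#' @param transcripts list of [TranscriptModel-class]; only non-coding
#'   entries are used.
#' @param genome genome [Biostrings::DNAStringSet].
#' @param tisSets named list of TIS call data.frames.
#' @param starts permitted start codons.
#' @param minReads read threshold for a translated call.
#' @param window matching half-window in nt.
#' @return data.frame of lncRNA ORFs with per-experiment `translated.*`
#'   columns, `votes`, and `twoVoted`.
#' @export
callLncrnaOrfs <- function(transcripts, genome, tisSets,
                           starts = startCodonSet(), minReads = 10L,
                           window = 1L) {
  lnc <- Filter(function(tx) is.na(tx@cdsStart), transcripts)
  parts <- lapply(lnc, function(tx) {
    seq <- splicedSequence(tx, genome)
    L <- nchar(seq)
    orfs <- enumerateOrfs(seq, starts, startMax = L - 5L, stopMax = L)
    if (!nrow(orfs)) return(NULL)
    data.frame(txId = tx@txId, contig = tx@contig, strand = tx@strand,
               gStart = transcriptToGenome(tx, orfs$startTx),
               startTx = orfs$startTx, stopTx = orfs$stopTx,
               length = orfs$stopTx + 2L - orfs$startTx + 1L,
               codon = orfs$codon, stringsAsFactors = FALSE)
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts))
    return(data.frame(txId = character(0), votes = integer(0),
                      twoVoted = logical(0)))
  rec <- do.call(rbind, parts)
  rownames(rec) <- NULL
  if (is.null(names(tisSets)))
    names(tisSets) <- vapply(tisSets, function(t) t$experiment[1], character(1))
  votes <- integer(nrow(rec))
  for (e in names(tisSets)) {
    hit <- tisMatch(rec$contig, rec$strand, rec$gStart, tisSets[[e]], window)
    translated <- attr(hit, "reads") >= minReads
    rec[[paste0("translated.", e)]] <- translated
    votes <- votes + as.integer(translated)
  }
  rec$votes <- votes
  rec$twoVoted <- votes >= 2L
  rec
}

#' Stratify positive uORFs by ribosome binding strength
#'
#' Binding strength is the number of footprinting reads at the start codon
#' normalized by transcript expression. The median (linear-interpolation
#' 50th percentile) of strengths among positives splits the set: strictly
#' above the median is `strong`, the rest `weak`. For each experiment and
#' class, the fraction of that experiment's detected positives that are
#' also detected in at least one other experiment is reported.
#'
#' @param labeled labeled catalog from [assignVotes()].
#' @param expression data.frame from [readExpression()].
#' @param positives logical mask of the positive set (default: 2-voted).
#' @return list with `strengths` (per-uORF data.frame with `strength` and
#'   `class`) and `overlap` (per experiment x class cross-detection rates).
#'   uORFs lacking (or with non-positive) expression are excluded and
#'   counted in `nExcluded`.
#' @export
stratifyBinding <- function(labeled, expression,
                            positives = labeled$partition == "two_voted") {
  expIds <- sub("^detected\\.", "",
                grep("^detected\\.", names(labeled), value = TRUE))
  pos <- labeled[positives, , drop = FALSE]
  expr <- expression$expression[match(pos$txId, expression$txId)]
  readCols <- paste0("reads.", expIds)
  totalReads <- rowSums(as.matrix(pos[, readCols, drop = FALSE]))
  usable <- !is.na(expr) & expr > 0
  nExcluded <- sum(!usable)
  pos <- pos[usable, , drop = FALSE]
  strength <- totalReads[usable] / expr[usable]
  med <- stats::quantile(strength, 0.5, type = 7, names = FALSE)
  cls <- ifelse(strength > med, "strong", "weak")
  detMat <- as.matrix(pos[, paste0("detected.", expIds), drop = FALSE])
  rows <- list()
  for (e in expIds) {
    de <- detMat[, paste0("detected.", e)]
    others <- detMat[, setdiff(colnames(detMat), paste0("detected.", e)),
                     drop = FALSE]
    cross <- rowSums(others) > 0
    for (cl in c("weak", "strong")) {
      sel <- de & cls == cl
      rows[[paste(e, cl)]] <- data.frame(
        experiment = e, class = cl, n = sum(sel),
        fracCross = if (sum(sel)) mean(cross[sel]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(strengths = data.frame(key = pos$key, strength = strength, class = cls,
                              stringsAsFactors = FALSE),
       overlap = do.call(rbind, rows), median = med, nExcluded = nExcluded)
}
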