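# Variant-driven uORF gain/loss: event detection from SNVs, the reference
# codon x interrupting-variant density matrix, rQTL enrichment, and the
# protein-expression contrast between gain and loss carriers.

#' Detect uORF start-codon gain and loss events from variants
#'
#' Loss: an SNV inside the start codon of a predicted-positive uORF whose
#' substituted codon leaves the configured codon set. Gain: an SNV in a
#' 5'UTR creating an ATG/CTG (by default) whose first in-frame stop lies
#' before the CDS end, i.e. a complete new uORF absent from the reference
#' scan; when a `scoreFun` is supplied, gains are restricted to new uORFs
#' it scores positive. All codon arithmetic is strand-aware (the alternate
#' allele is complemented on minus-strand transcripts). Variants whose
#' reference allele does not match the genome are skipped and counted
#' (assembly check); non-SNVs are set aside in a `multiEffect` channel.
#'
#' @param scored labeled/scored catalog data.frame containing catalog
#'   columns plus a logical `label` column (predicted positive).
#' @param transcripts list of [TranscriptModel-class].
#' @param genome genome [Biostrings::DNAStringSet].
#' @param variants data.frame from [readVariants()].
#' @param gainCodons codons whose creation counts as a gain (default
#'   ATG/CTG, the predicted-positive gain set).
#' @param lossCodons codon set defining membership for loss (default all
#'   ten start codons).
#' @param scoreFun optional `function(recordRow, transcript)` returning
#'   `TRUE` if a would-be gained uORF is predicted positive.
#' @return list `events` (data.frame: variant fields, `event`, `refCodon`,
#'   `codonPos`, `altBase`, `newCodon`, `uorfKey`, `topology`),
#'   `multiEffect` (non-SNV variants), `nRefMismatch`.
#' @export
detectEvents <- function(scored, transcripts, genome, variants,
                         gainCodons = c("ATG", "CTG"),
                         lossCodons = startCodonSet(),
                         scoreFun = NULL) {
  snv <- variants[variants$isSnv, , drop = FALSE]
  multi <- variants[!variants$isSnv, , drop = FALSE]
  # assembly check
  refOk <- vapply(seq_len(nrow(snv)), function(i) {
    ctg <- snv$contig[i]
    if (!ctg %in% names(genome)) return(FALSE)
    substr(as.character(genome[[ctg]]), snv$pos[i], snv$pos[i]) == snv$ref[i]
  }, logical(1))
  nRefMismatch <- sum(!refOk)
  snv <- snv[refOk, , drop = FALSE]
  events <- list()

  # --- loss events: SNVs inside predicted-positive start codons ----------
  pos <- scored[scored$label %in% TRUE, , drop = FALSE]
  if (nrow(pos) && nrow(snv)) {
    for (i in seq_len(nrow(pos))) {
      tx <- transcripts[[pos$txId[i]]]
      codonG <- transcriptToGenome(tx, pos$startTx[i]:(pos$startTx[i] + 2L))
      hits <- which(snv$contig == pos$contig[i] & snv$pos %in% codonG)
      for (h in hits) {
        cp <- match(snv$pos[h], codonG)  # codon position 1..3, tx orientation
        altTx <- if (tx@strand == "-") complementBase(snv$alt[h]) else snv$alt[h]
        ref <- pos$codon[i]
        newCodon <- ref
        substr(newCodon, cp, cp) <- altTx
        if (ref %in% lossCodons && !newCodon %in% lossCodons) {
          events[[length(events) + 1L]] <- data.frame(
            id = snv$id[h], contig = snv$contig[h], pos = snv$pos[h],
            ref = snv$ref[h], alt = snv$alt[h], event = "loss",
            refCodon = ref, codonPos = cp, altBase = altTx,
            newCodon = newCodon, uorfKey = pos$key[i],
            topology = pos$topology[i], stringsAsFactors = FALSE)
        }
      }
    }
  }

  # --- gain events: SNVs in 5'UTRs creating a new start codon ------------
  if (nrow(snv)) {
    coding <- Filter(function(tx) !is.na(tx@cdsStart) && tx@cdsStart > 3L,
                     transcripts)
    for (tx in coding) {
      utrG <- transcriptToGenome(tx, seq_len(tx@cdsStart - 1L))
      hits <- which(snv$contig == tx@contig & snv$pos %in% utrG)
      if (!length(hits)) next
      refSeq <- splicedSequence(tx, genome)
      # a gain needs a uORF that did not already start with a gain-set
      # codon at these coordinates (ACG -> ATG upgrades an existing weak
      # start and still counts as an ATG gain)
      refScan <- scanTranscript(tx, refSeq, starts = gainCodons)
      for (h in hits) {
        tpos <- genomeToTranscript(tx, snv$pos[h])
        altTx <- if (tx@strand == "-") complementBase(snv$alt[h]) else snv$alt[h]
        altSeq <- refSeq
        substr(altSeq, tpos, tpos) <- altTx
        altScan <- scanTranscript(tx, altSeq, starts = gainCodons)
        created <- altScan[!altScan$key %in% refScan$key &
                             altScan$startTx <= tpos &
                             altScan$startTx + 2L >= tpos &
                             altScan$topology != "shared_stop_extension", ,
                           drop = FALSE]
        for (j in seq_len(nrow(created))) {
          if (!is.null(scoreFun) && !isTRUE(scoreFun(created[j, ], tx))) next
          cp <- tpos - created$startTx[j] + 1L
          refCodon <- substr(refSeq, created$startTx[j],
                             created$startTx[j] + 2L)
          events[[length(events) + 1L]] <- data.frame(
            id = snv$id[h], contig = snv$contig[h], pos = snv$pos[h],
            ref = snv$ref[h], alt = snv$alt[h], event = "gain",
            refCodon = refCodon, codonPos = cp, altBase = altTx,
            newCodon = created$codon[j], uorfKey = created$key[j],
            topology = created$topology[j], stringsAsFactors = FALSE)
        }
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(id = character(0), contig = character(0),
                        pos = integer(0), ref = character(0),
                        alt = character(0), event = character(0),
                        refCodon = character(0), codonPos = integer(0),
                        altBase = character(0), newCodon = character(0),
                        uorfKey = character(0), topology = character(0),
                        stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  list(events = ev, multiEffect = multi, nRefMismatch = nRefMismatch)
}

#' Reference codon x interrupting variant density matrix
#'
#' Rows are the ten permitted start codons; columns are (codon position 1-3)
#' x (alternate base A/C/G/T), in transcript orientation. Identity cells
#' (alternate equal to the reference base) are structurally zero; the
#' total equals the event count.
#'
#' @param events event data.frame from [detectEvents()] (typically the
#'   losses).
#' @return 10 x 12 integer matrix with dimnames.
#' @export
densityMatrix <- function(events) {
  codons <- startCodonSet()
  cols <- paste(rep(1:3, each = 4), rep(c("A", "C", "G", "T"), 3), sep = ":")
  m <- matrix(0L, length(codons), length(cols),
              dimnames = list(codons, cols))
  for (i in seq_len(nrow(events))) {
    r <- events$refCodon[i]
    cc <- paste(events$codonPos[i], events$altBase[i], sep = ":")
    if (r %in% codons && cc %in% cols) m[r, cc] <- m[r, cc] + 1L
  }
  m
}

#' rQTL enrichment among predicted-positive uORFs
#'
#' Of the rQTLs (ribosome-occupancy QTLs) that interrupt a scored uORF
#' start codon, what fraction hit a positively scored uORF, versus the
#' baseline rate at which random hits would do so. Reports the observed
#' fraction, the fold enrichment, and a two-sided exact binomial p-value.
#'
#' @param nPositive number of rQTLs hitting positively scored uORFs.
#' @param nTotal total number of rQTLs hitting scored uORFs.
#' @param baseline baseline positive fraction (the genome-wide share of
#'   uORFs classified positive).
#' @return list `observed`, `observedPct` (integer percent, as printed),
#'   `fold`, `pValue`.
#' @export
#' @examples
#' rqtlEnrichment(21, 44, baseline = 0.149)
rqtlEnrichment <- function(nPositive, nTotal, baseline) {
  if (nTotal == 0) stop("no rQTLs supplied")
  obs <- nPositive / nTotal
  list(observed = obs, observedPct = round(100 * obs),
       fold = obs / baseline,
       pValue = stats::binom.test(nPositive, nTotal, baseline)$p.value)
}

#' Annotate an rQTL list against a scored catalog and test enrichment
#'
#' Each rQTL is matched to the scored uORF start codon it interrupts (same
#' contig, genomic position within the codon's three bases); rQTLs hitting
#' no start codon are dropped with a count.
#'
#' @param rqtls data.frame with `contig`, `pos`.
#' @param scored scored catalog data.frame with `label` column.
#' @param transcripts list of [TranscriptModel-class].
#' @param baseline baseline positive fraction; default: share of positive
#'   labels in `scored`.
#' @return As [rqtlEnrichment()], plus `nUnmatched`.
#' @export
rqtlEnrichmentFromVariants <- function(rqtls, scored, transcripts,
                                       baseline = mean(scored$label)) {
  hitLabel <- rep(NA, nrow(rqtls))
  for (i in seq_len(nrow(scored))) {
    tx <- transcripts[[scored$txId[i]]]
    codonG <- transcriptToGenome(tx, scored$startTx[i]:(scored$startTx[i] + 2L))
    m <- which(rqtls$contig == scored$contig[i] & rqtls$pos %in% codonG)
    hitLabel[m] <- scored$label[i]
  }
  matched <- !is.na(hitLabel)
  out <- rqtlEnrichment(sum(hitLabel[matched]), sum(matched), baseline)
  out$nUnmatched <- sum(!matched)
  out
}

#' Protein-expression contrast between uORF gain and loss variants
#'
#' Observation unit: one (variant, carrier individual) pair, with the
#' carrier's normalized protein-expression value for the affected gene.
#' Events are filtered to variants carried by more than `sharingThreshold`
#' individuals; a pooled-variance two-sample t statistic compares
#' gain-associated and loss-associated observations. A second contrast
#' splits the loss events by uORF topology (CDS-overlapping vs fully
#' upstream).
#'
#' @param events event data.frame from [detectEvents()].
#' @param genotypes long data.frame `id` (variant), `individual` (carriers
#'   only).
#' @param protein long data.frame `id`, `individual`, `value`.
#' @param sharingThreshold keep variants carried by strictly more than
#'   this many individuals (default 10).
#' @return list `contrast` (meanGain, meanLoss, t, df, p, nGain, nLoss)
#'   and `topologyContrast` (loss events only: CDS-overlapping vs
#'   upstream), either `NULL` when a group is empty in the secondary
#'   contrast.
#' @export
expressionContrast <- function(events, genotypes, protein,
                               sharingThreshold = 10) {
  if (!"topology" %in% names(events)) events$topology <- NA_character_
  carriers <- table(genotypes$id)
  keepIds <- names(carriers)[carriers > sharingThreshold]
  ev <- events[events$id %in% keepIds, , drop = FALSE]
  obs <- merge(ev[, c("id", "event", "topology")],
               protein, by = "id")
  gain <- obs$value[obs$event == "gain"]
  loss <- obs$value[obs$event == "loss"]
  if (!length(gain)) stop("gain group is empty after sharing filter")
  if (!length(loss)) stop("loss group is empty after sharing filter")
  tt <- stats::t.test(gain, loss, var.equal = TRUE)
  contrast <- list(meanGain = mean(gain), meanLoss = mean(loss),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value, nGain = length(gain),
                   nLoss = length(loss))
  lossObs <- obs[obs$event == "loss", , drop = FALSE]
  ov <- lossObs$value[lossObs$topology == "cds_overlap"]
  up <- lossObs$value[lossObs$topology == "upstream"]
  topologyContrast <- NULL
  if (length(ov) > 1L && length(up) > 1L) {
    tt2 <- stats::t.test(ov, up, var.equal = TRUE)
    topologyContrast <- list(meanOverlap = mean(ov), meanUpstream = mean(up),
                             t = unname(tt2$statistic),
                             df = unname(tt2$parameter), p = tt2$p.value,
                             nOverlap = length(ov), nUpstream = length(up))
  }
  list(contrast = contrast, topologyContrast = topologyContrast)
}
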