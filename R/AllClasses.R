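#' @import methods
NULL

# ---------------------------------------------------------------------------
# TranscriptModel
# ---------------------------------------------------------------------------

#' Spliced transcript model with UTR/CDS structure
#'
#' A single transcript: ordered exons in genomic coordinates (1-based
#' inclusive, listed 5'->3' in transcript orientation, so decreasing for the
#' minus strand) plus the CDS boundaries expressed in transcript coordinates.
#' Non-coding (lncRNA) transcripts carry `NA` CDS boundaries.
#'
#' All transcript-space coordinates in this package are 1-based inclusive.
#'
#' @slot txId transcript identifier
#' @slot geneId gene identifier
#' @slot contig contig (chromosome) name
#' @slot strand `"+"` or `"-"`
#' @slot exonStarts,exonEnds integer vectors of genomic exon boundaries
#' @slot cdsStart,cdsEnd CDS first/last base in transcript coordinates
#'   (the CDS here includes its stop codon); `NA` for non-coding transcripts
#' @slot biotype `"coding"` or `"lncRNA"`
#'
#' @seealso [transcriptModel()], [splicedSequence()], [transcriptToGenome()]
#' @export
setClass("TranscriptModel", representation(
  txId = "character",
  geneId = "character",
  contig = "character",
  strand = "character",
  exonStarts = "integer",
  exonEnds = "integer",
  cdsStart = "integer",
  cdsEnd = "integer",
  biotype = "character"
))

setValidity("TranscriptModel", function(object) {
  msg <- character(0)
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be '+' or '-'")
  ns <- length(object@exonStarts)
  if (ns == 0L || ns != length(object@exonEnds))
    msg <- c(msg, "exonStarts/exonEnds must be non-empty and equal length")
  else {
    if (any(object@exonEnds < object@exonStarts))
      msg <- c(msg, "exon end before exon start")
    if (ns > 1L) {
      # 5'->3' in transcript orientation; non-overlapping
      if (object@strand == "+" &&
          any(diff(object@exonStarts) <= 0 |
              object@exonStarts[-1] <= object@exonEnds[-ns]))
        msg <- c(msg, "plus-strand exons must be increasing and non-overlapping")
      if (object@strand == "-" &&
          any(diff(object@exonStarts) >= 0 |
              object@exonEnds[-1] >= object@exonStarts[-ns]))
        msg <- c(msg, "minus-strand exons must be decreasing and non-overlapping")
    }
  }
  txLen <- sum(object@exonEnds - object@exonStarts + 1L)
  if (!is.na(object@cdsStart)) {
    if (object@cdsStart < 1L || object@cdsEnd > txLen || object@cdsStart > object@cdsEnd)
      msg <- c(msg, "CDS boundaries outside transcript")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TranscriptModel
#'
#' @param txId,geneId transcript and gene identifiers.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param exonStarts,exonEnds genomic exon boundaries (1-based inclusive),
#'   ordered 5'->3' in transcript orientation.
#' @param cdsStart,cdsEnd CDS boundaries in transcript coordinates (stop
#'   codon included); leave `NA` for non-coding transcripts.
#' @param biotype `"coding"` or `"lncRNA"`.
#' @return A [TranscriptModel-class] object.
#' @export
#' @examples
#' tx <- transcriptModel("tx1", "g1", "chr1", "+", 101L, 130L,
#'                       cdsStart = 11L, cdsEnd = 28L)
#' txLength(tx)
transcriptModel <- function(txId, geneId, contig, strand, exonStarts, exonEnds,
                            cdsStart = NA_integer_, cdsEnd = NA_integer_,
                            biotype = if (is.na(cdsStart)) "lncRNA" else "coding") {
  new("TranscriptModel",
      txId = as.character(txId), geneId = as.character(geneId),
      contig = as.character(contig), strand = strand,
      exonStarts = as.integer(exonStarts), exonEnds = as.integer(exonEnds),
      cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd),
      biotype = biotype)
}

#' @describeIn transcriptModel total spliced transcript length (nt)
#' @param x a `TranscriptModel`
#' @export
txLength <- function(x) sum(x@exonEnds - x@exonStarts + 1L)

#' @describeIn transcriptModel transcript identifier
#' @export
txId <- function(x) x@txId

#' @describeIn transcriptModel 5'UTR length in nt (`cdsStart - 1`); `NA` for
#'   non-coding transcripts
#' @export
utrLength <- function(x) x@cdsStart - 1L

setMethod("show", "TranscriptModel", function(object) {
  cds <- if (is.na(object@cdsStart)) "non-coding"
         else sprintf("CDS %d..%d", object@cdsStart, object@cdsEnd)
  cat(sprintf("TranscriptModel %s (%s) %s:%s %d exon(s), %d nt, %s\n",
              object@txId, object@biotype, object@contig, object@strand,
              length(object@exonStarts), txLength(object), cds))
})

# ---------------------------------------------------------------------------
# UorfCatalog
# ---------------------------------------------------------------------------

#' Catalog of scanned uORFs
#'
#' Container for the per-uORF records produced by [scanUorfs()]. Each row
#' describes one candidate uORF: its genomic-coordinate identity, start
#' codon, transcript-space offsets, topology relative to the CDS, and
#' reading frame. The `stats` slot accumulates bookkeeping counters
#' (transcripts dropped at load, records removed by cleansing, duplicates
#' collapsed).
#'
#' @slot records data.frame with columns `key`, `contig`, `strand`,
#'   `gStart`, `gStop`, `txId`, `startTx`, `stopTx`, `length`, `codon`,
#'   `topology`, `frame`
#' @slot stats named list of integer counters
#' @seealso [scanUorfs()], [applyCleansing()], [deduplicateUorfs()]
#' @export
setClass("UorfCatalog", representation(records = "data.frame", stats = "list"))

catalogColumns <- function() {
  c("key", "contig", "strand", "gStart", "gStop", "txId", "startTx",
    "stopTx", "length", "codon", "topology", "frame")
}

setValidity("UorfCatalog", function(object) {
  rec <- object@records
  miss <- setdiff(catalogColumns(), names(rec))
  if (length(miss))
    return(paste("missing record columns:", paste(miss, collapse = ", ")))
  if (nrow(rec)) {
    if (any(rec$stopTx %% 3L != rec$startTx %% 3L))
      return("stop codon out of frame with start codon")
    if (any(rec$length != rec$stopTx + 2L - rec$startTx + 1L))
      return("length inconsistent with start/stop offsets")
    if (!all(rec$topology %in% c("upstream", "cds_overlap", "shared_stop_extension")))
      return("unknown topology label")
    if (!all(rec$frame %in% 0:2)) return("frame must be 0, 1 or 2")
  }
  TRUE
})

#' Construct a UorfCatalog
#' @param records catalog record data.frame (see [UorfCatalog-class]).
#' @param stats named list of bookkeeping counters.
#' @return A `UorfCatalog`.
#' @export
UorfCatalog <- function(records, stats = list()) {
  rownames(records) <- NULL
  new("UorfCatalog", records = records, stats = stats)
}

#' @describeIn UorfCatalog record data.frame accessor
#' @param x a `UorfCatalog`
#' @export
uorfRecords <- function(x) x@records

#' @describeIn UorfCatalog bookkeeping counters accessor
#' @export
scanStats <- function(x) x@stats

#' @export
setMethod("length", "UorfCatalog", function(x) nrow(x@records))

setMethod("show", "UorfCatalog", function(object) {
  rec <- object@records
  cat(sprintf("UorfCatalog with %d uORF record(s)\n", nrow(rec)))
  if (nrow(rec)) {
    cat("  topology:",
        paste(sprintf("%s=%d", names(table(rec$topology)), table(rec$topology)),
              collapse = " "), "\n")
    top <- sort(table(rec$codon), decreasing = TRUE)
    cat("  top codons:",
        paste(sprintf("%s=%d", names(head(top, 4)), head(top, 4)), collapse = " "),
        "\n")
  }
  if (length(object@stats))
    cat("  stats:",
        paste(sprintf("%s=%s", names(object@stats), unlist(object@stats)),
              collapse = " "), "\n")
})

# ---------------------------------------------------------------------------
# NaiveBayesModel
# ---------------------------------------------------------------------------

#' Positive-unlabeled Naive-Bayes model over discretized uORF attributes
#'
#' Stores the class prior and, for every feature, the smoothed bin
#' likelihoods under the positive and the unlabeled class. Scoring computes
#' the natural-log odds `log(p_pos / p_neg)` with `p_pos = P_pos *
#' prod_i p(A_i | pos)` and `p_neg = (1 - P_pos) * prod_i p(A_i | unl)`;
#' a score above 0 is a positive call.
#'
#' @slot prior prior probability of the positive class (`P_pos`)
#' @slot likePos,likeUnl named lists (one element per feature) of named
#'   numeric vectors of bin likelihoods; each vector sums to 1
#' @slot smoothing additive smoothing constant used at fit time
#' @slot features character vector of feature names, fixing feature order
#' @seealso [nbFit()], [nbScore()], [selectPrior()]
#' @export
setClass("NaiveBayesModel", representation(
  prior = "numeric", likePos = "list", likeUnl = "list",
  smoothing = "numeric", features = "character"))

setValidity("NaiveBayesModel", function(object) {
  if (object@prior <= 0 || object@prior >= 1) return("prior must be in (0,1)")
  for (f in object@features) {
    for (tab in list(object@likePos[[f]], object@likeUnl[[f]])) {
      if (is.null(tab)) return(sprintf("missing likelihood table for '%s'", f))
      if (any(tab <= 0)) return(sprintf("non-positive likelihood in '%s'", f))
      if (abs(sum(tab) - 1) > 1e-9)
        return(sprintf("likelihoods for '%s' do not sum to 1", f))
    }
  }
  TRUE
})

setMethod("show", "NaiveBayesModel", function(object) {
  cat(sprintf("NaiveBayesModel: %d feature(s), P_pos = %.3f, smoothing k = %g\n",
              length(object@features), object@prior, object@smoothing))
  cat("  features:", paste(object@features, collapse = ", "), "\n")
})

#' @describeIn NaiveBayesModel prior probability accessor
#' @param x a `NaiveBayesModel`
#' @export
nbPrior <- function(x) x@prior

#' @describeIn NaiveBayesModel per-feature likelihood tables,
#'   `list(pos = ..., unl = ...)`
#' @param feature feature name
#' @export
nbLikelihoods <- function(x, feature) {
  list(pos = x@likePos[[feature]], unl = x@likeUnl[[feature]])
}

# ---------------------------------------------------------------------------
# MarkRecaptureSeries
# ---------------------------------------------------------------------------

#' Sequential mark-recapture series
#'
#' Sample sizes `C_t`, cumulative marked counts `M_t` (individuals marked
#' before sample `t`) and recaptures `R_t` (marked individuals re-caught in
#' sample `t`) for a closed-population estimate. In the uORF setting each
#' ribosome-profiling experiment is one sample and "marking" is detection in
#' an earlier experiment.
#'
#' @slot C,M,R numeric vectors of equal length
#' @seealso [markRecaptureSeries()], [schnabel()], [schumacherEschmeyer()]
#' @export
setClass("MarkRecaptureSeries",
         representation(C = "numeric", M = "numeric", R = "numeric"))

setValidity("MarkRecaptureSeries", function(object) {
  C <- object@C; M <- object@M; R <- object@R
  if (length(C) == 0L) return(TRUE)  # under construction
  if (length(C) != length(M) || length(C) != length(R))
    return("C, M, R must be non-empty and of equal length")
  if (any(C < 0) || any(M < 0) || any(R < 0)) return("counts must be non-negative")
  if (M[1] != 0) return("M_1 must be 0 (nothing marked before the first sample)")
  if (any(R > pmin(C, M))) return("R_t cannot exceed min(C_t, M_t)")
  S <- length(C)
  if (S > 1L && any(abs(M[-1] - (M[-S] + C[-S] - R[-S])) > 1e-9))
    return("M must satisfy M_{t+1} = M_t + C_t - R_t")
  TRUE
})

#' Construct a MarkRecaptureSeries
#'
#' If `M` is omitted it is derived from the recurrence `M_1 = 0`,
#' `M_{t+1} = M_t + C_t - R_t` (every unmarked capture is marked and
#' released).
#'
#' @param C sample sizes.
#' @param R recaptures per sample.
#' @param M cumulative marked counts before each sample (optional).
#' @return A [MarkRecaptureSeries-class] object.
#' @export
#' @examples
#' markRecaptureSeries(C = c(100, 100), R = c(0, 50))
markRecaptureSeries <- function(C, R, M = NULL) {
  C <- as.numeric(C); R <- as.numeric(R)
  if (is.null(M)) {
    M <- numeric(length(C))
    if (length(C) > 1L)
      for (t in 2:length(C)) M[t] <- M[t - 1L] + C[t - 1L] - R[t - 1L]
  }
  # `C = C` would partially match new()'s `Class` argument; fill it after
  obj <- new("MarkRecaptureSeries", M = as.numeric(M), R = R)
  obj@C <- C
  validObject(obj)
  obj
}

setMethod("show", "MarkRecaptureSeries", function(object) {
  cat(sprintf("MarkRecaptureSeries with %d sample(s)\n", length(object@C)))
  print(data.frame(t = seq_along(object@C), C = object@C, M = object@M,
                   R = object@R))
})
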