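# Per-uORF attributes, MDLP (Fayyad-Irani) entropy discretization, and
# Kolmogorov-Smirnov feature prioritization.

#' Compute per-uORF attributes
#'
#' Implements the attribute set discussed in the main analysis: start/stop
#' codon conservation (mean per-base score over the codon), distance from
#' the uORF stop to the CDS start (`cdsStart - stopEnd`), distance from the
#' 5' cap to the uORF start (`startTx - 1`), 5'UTR length, uORF length,
#' number of internal ATG/near-cognate 3-mers (any frame, positions
#' 2..L-2 of the uORF sequence), GC content, start-codon identity
#' (categorical), number of other scanned uORFs on the same transcript,
#' transcript expression, and a Kozak-like start-context score (purine at
#' -3, G at +4; 0/0.5/1). Attributes whose input track is absent are `NA`
#' ("missing") and are skipped in the Naive-Bayes product at scoring time.
#'
#' @param catalog a [UorfCatalog-class] or labeled catalog data.frame.
#' @param transcripts list of [TranscriptModel-class].
#' @param genome genome [Biostrings::DNAStringSet].
#' @param conservation optional per-contig score vectors from
#'   [loadConservation()].
#' @param expression optional data.frame from [readExpression()].
#' @return data.frame keyed by `key`: one row per uORF, one column per
#'   attribute.
#' @export
computeFeatures <- function(catalog, transcripts, genome,
                            conservation = NULL, expression = NULL) {
  rec <- if (is(catalog, "UorfCatalog")) uorfRecords(catalog) else catalog
  n <- nrow(rec)
  seqCache <- new.env(parent = emptyenv())
  getSeq <- function(id) {
    s <- seqCache[[id]]
    if (is.null(s)) {
      s <- splicedSequence(transcripts[[id]], genome)
      assign(id, s, envir = seqCache)
    }
    s
  }
  consAt <- function(tx, posVec) {
    if (is.null(conservation)) return(NA_real_)
    v <- conservation[[tx@contig]]
    if (is.null(v)) return(NA_real_)
    mean(v[transcriptToGenome(tx, posVec)])
  }

  consStart <- consStop <- distToCds <- distFromCap <- utrLen <- gc <-
    internal <- kozak <- numeric(n)
  uorfSeqList <- character(n)
  for (i in seq_len(n)) {
    tx <- transcripts[[rec$txId[i]]]
    seq <- getSeq(rec$txId[i])
    p <- rec$startTx[i]; q <- rec$stopTx[i]
    uorf <- substr(seq, p, q + 2L)
    uorfSeqList[i] <- uorf
    consStart[i] <- consAt(tx, p:(p + 2L))
    consStop[i] <- consAt(tx, q:(q + 2L))
    distToCds[i] <- tx@cdsStart - (q + 2L)
    distFromCap[i] <- p - 1L
    utrLen[i] <- tx@cdsStart - 1L
    gc[i] <- gcContent(uorf)
    internal[i] <- internalStartCount(uorf)
    kozak[i] <- kozakContext(seq, p)
  }
  expr <- if (is.null(expression)) rep(NA_real_, n)
          else expression$expression[match(rec$txId, expression$txId)]
  perTx <- table(rec$txId)
  data.frame(key = rec$key,
             consStart = consStart, consStop = consStop,
             distToCds = distToCds, distFromCap = distFromCap,
             utrLength = utrLen, uorfLength = rec$length,
             nInternalStarts = internal, gcContent = gc,
             startCodon = rec$codon,
             nUorfsOnTx = as.integer(perTx[rec$txId]),
             expression = expr, kozakScore = kozak,
             stringsAsFactors = FALSE)
}

#' @describeIn computeFeatures GC fraction of a sequence
#' @param seq nucleotide string
#' @export
gcContent <- function(seq) {
  if (!nchar(seq)) return(NA_real_)
  lengths(regmatches(seq, gregexpr("[GC]", seq))) / nchar(seq)
}

#' @describeIn computeFeatures count of start-set 3-mers at positions
#'   `2..L-2` of the uORF sequence (any frame, downstream of the start
#'   codon's first base)
#' @param starts permitted start codons
#' @export
internalStartCount <- function(seq, starts = startCodonSet()) {
  tm <- threemers(seq)
  if (length(tm) < 2L) return(0L)
  sum(tm[-1L] %in% starts)
}

# Kozak-like context: purine at -3 and G at +4 relative to the start codon
# (transcript coordinates); each contributes 0.5. Out-of-range positions
# contribute 0.
kozakContext <- function(seq, p) {
  s <- 0
  if (p >= 4L && substr(seq, p - 3L, p - 3L) %in% c("A", "G")) s <- s + 0.5
  if (p + 3L <= nchar(seq) && substr(seq, p + 3L, p + 3L) == "G") s <- s + 0.5
  s
}

# ---------------------------------------------------------------------------
# MDLP discretization (Fayyad & Irani)
# ---------------------------------------------------------------------------

# Entropy-based binary split search on one node of sorted data.
# Candidate cuts are midpoints between adjacent distinct values; the
# maximum-gain cut is accepted iff
#   gain > (log2(n-1) + delta) / n,
#   delta = log2(3^k - 2) - (k*E - k1*E1 - k2*E2)
# with k the number of classes present in the node (Fayyad-Irani MDL
# criterion). Ties in gain resolve to the smallest cut value.
mdlpNode <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(NULL)
  boundary <- which(diff(x) > 0)
  if (!length(boundary)) return(NULL)
  cumPos <- cumsum(y)
  nPos <- cumPos[n]
  ent <- entropy2(c(nPos, n - nPos))
  n1 <- boundary
  pos1 <- cumPos[boundary]
  h <- function(p, m) {
    e <- numeric(length(p))
    ok <- m > 0
    pr <- p[ok] / m[ok]
    e[ok] <- -ifelse(pr > 0, pr * log2(pr), 0) -
      ifelse(1 - pr > 0, (1 - pr) * log2(1 - pr), 0)
    e
  }
  e1 <- h(pos1, n1)
  e2 <- h(nPos - pos1, n - n1)
  gain <- ent - (n1 * e1 + (n - n1) * e2) / n
  best <- which.max(gain)  # first maximum = smallest cut
  k <- sum(c(nPos, n - nPos) > 0)
  k1 <- sum(c(pos1[best], n1[best] - pos1[best]) > 0)
  k2 <- sum(c(nPos - pos1[best], (n - n1[best]) - (nPos - pos1[best])) > 0)
  delta <- log2(3^k - 2) - (k * ent - k1 * e1[best] - k2 * e2[best])
  if (gain[best] <= (log2(n - 1) + delta) / n) return(NULL)
  list(cut = (x[boundary[best]] + x[boundary[best] + 1L]) / 2,
       idx = boundary[best])
}

#' MDLP entropy discretization of one attribute
#'
#' Recursive entropy-minimizing binary splitting with the Fayyad-Irani
#' minimum-description-length acceptance criterion, computed between the
#' positive and unlabeled classes. Deterministic: identical inputs yield
#' identical cut points. A constant feature, or one where no split passes
#' the MDL test, yields zero cuts and sets the fallback flag.
#'
#' @param x numeric attribute values (`NA` allowed; ignored).
#' @param y class labels coercible to logical (positive = `TRUE`).
#' @return list with `cuts` (strictly increasing numeric vector, possibly
#'   empty) and `fallback` (`TRUE` iff no cut was accepted).
#' @export
#' @examples
#' mdlpDiscretize(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
mdlpDiscretize <- function(x, y) {
  y <- as.logical(y)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  cuts <- numeric(0)
  recurse <- function(lo, hi) {
    node <- mdlpNode(x[lo:hi], y[lo:hi])
    if (is.null(node)) return(invisible())
    cuts <<- c(cuts, node$cut)
    recurse(lo, lo + node$idx - 1L)
    recurse(lo + node$idx, hi)
  }
  if (length(x) >= 2L) recurse(1L, length(x))
  list(cuts = sort(cuts), fallback = length(cuts) == 0L)
}

#' Apply a discretization to values
#'
#' Maps every finite value to exactly one bin via `findInterval`; values
#' outside the training range fall into the first or last bin (clamping).
#' `NA` values stay `NA`.
#'
#' @param x numeric values.
#' @param cuts cut points from [mdlpDiscretize()].
#' @return Integer bin indices in `1..(length(cuts) + 1)`.
#' @export
applyDiscretization <- function(x, cuts) {
  findInterval(x, cuts) + 1L
}

#' Discretize a feature matrix
#'
#' Numeric attributes are discretized with [mdlpDiscretize()] against the
#' supplied class labels; categorical attributes (character/factor) bypass
#' MDLP and use one bin per category.
#'
#' @param fm feature data.frame from [computeFeatures()].
#' @param labels logical positive-class labels (one per row).
#' @param features attribute columns to use (default: all but `key`).
#' @return list with `binned` (data.frame of integer bins / factors) and
#'   `scheme` (per-feature list: `cuts` + `fallback`, or `levels`).
#' @export
discretizeFeatures <- function(fm, labels,
                               features = setdiff(names(fm), "key")) {
  scheme <- list()
  binned <- fm[, "key", drop = FALSE]
  for (f in features) {
    v <- fm[[f]]
    if (is.numeric(v)) {
      d <- mdlpDiscretize(v, labels)
      scheme[[f]] <- d
      binned[[f]] <- applyDiscretization(v, d$cuts)
    } else {
      lev <- sort(unique(v[!is.na(v)]))
      scheme[[f]] <- list(levels = lev)
      binned[[f]] <- as.integer(factor(v, levels = lev))
    }
  }
  list(binned = binned, scheme = scheme)
}

# number of bins a scheme entry defines
schemeBins <- function(entry) {
  if (!is.null(entry$levels)) length(entry$levels) else length(entry$cuts) + 1L
}

#' Rank attributes by the two-sample Kolmogorov-Smirnov statistic
#'
#' For each numeric attribute, `D = sup |ECDF_pos - ECDF_unl|` between the
#' positive and unlabeled values; larger `D` means greater power to
#' distinguish the sets. Attributes are ranked in descending `D`.
#' Categorical attributes, and attributes with an all-missing group, are
#' flagged and ranked last.
#'
#' @param fm feature data.frame from [computeFeatures()].
#' @param labels logical positive-class labels.
#' @param features attribute columns to rank.
#' @return data.frame `feature`, `ks`, `p`, `rank`, `flagged`, sorted by
#'   rank.
#' @export
ksRank <- function(fm, labels, features = setdiff(names(fm), "key")) {
  rows <- lapply(features, function(f) {
    v <- fm[[f]]
    if (!is.numeric(v))
      return(data.frame(feature = f, ks = NA_real_, p = NA_real_,
                        flagged = TRUE, stringsAsFactors = FALSE))
    a <- v[labels & !is.na(v)]
    b <- v[!labels & !is.na(v)]
    if (!length(a) || !length(b))
      return(data.frame(feature = f, ks = NA_real_, p = NA_real_,
                        flagged = TRUE, stringsAsFactors = FALSE))
    kt <- suppressWarnings(stats::ks.test(a, b))
    data.frame(feature = f, ks = unname(kt$statistic), p = kt$p.value,
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$flagged, -out$ks, out$feature), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
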