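# Positive-unlabeled Naive-Bayes classification of uORFs: fitting bin
# likelihoods from 2-voted positives vs unlabeled examples, F1-maximizing
# prior selection, log-odds scoring, the separate peptide-feature score,
# and leave-one-experiment-out validation.

#' Fit the positive-unlabeled Naive-Bayes model
#'
#' Likelihoods are additive-smoothed empirical bin frequencies:
#' `p(bin | class) = (count + k) / (n_class + k * nBins)`, computed over
#' non-missing values of each feature. The positive class is by default the
#' 2-voted set; everything else in `labels == FALSE` is the unlabeled set.
#'
#' @param binned discretized feature data.frame (integer bins; `NA`
#'   allowed), e.g. `discretizeFeatures(...)$binned`.
#' @param labels logical vector, `TRUE` for the positive (2-voted) set.
#' @param prior prior probability `P_pos` (default 0.5; see
#'   [selectPrior()] -- the study's operating point was 0.61).
#' @param k additive smoothing constant (default 1).
#' @param scheme discretization scheme (fixes the number of bins per
#'   feature even when a bin is unobserved); if `NULL`, bins observed in
#'   the data define the support.
#' @return A [NaiveBayesModel-class].
#' @export
nbFit <- function(binned, labels, prior = 0.5, k = 1,
                  scheme = NULL) {
  if (!any(labels)) stop("positive set is empty; cannot fit")
  features <- setdiff(names(binned), "key")
  likePos <- likeUnl <- list()
  for (f in features) {
    v <- binned[[f]]
    nb <- if (!is.null(scheme) && !is.null(scheme[[f]]))
      schemeBins(scheme[[f]]) else max(v, na.rm = TRUE)
    bins <- seq_len(max(nb, 1L))
    cntP <- tabulate(v[labels & !is.na(v)], nbins = length(bins))
    cntU <- tabulate(v[!labels & !is.na(v)], nbins = length(bins))
    likePos[[f]] <- stats::setNames(
      (cntP + k) / (sum(cntP) + k * length(bins)), bins)
    likeUnl[[f]] <- stats::setNames(
      (cntU + k) / (sum(cntU) + k * length(bins)), bins)
  }
  new("NaiveBayesModel", prior = prior, likePos = likePos,
      likeUnl = likeUnl, smoothing = k, features = features)
}

#' Score uORFs with a fitted model
#'
#' Computes `p_pos = P_pos * prod_i p(A_i|pos)` and
#' `p_neg = (1 - P_pos) * prod_i p(A_i|unl)` in log space and the
#' natural-log odds `score = log(p_pos / p_neg)`. Missing features are
#' skipped (the Naive-Bayes factorization permits dropping factors); bin
#' indices outside the trained support are clamped to the nearest bin and
#' counted. The predicted label is positive iff `score > 0` (strict).
#'
#' @param model a [NaiveBayesModel-class].
#' @param binned discretized feature data.frame matching the model's
#'   scheme.
#' @return data.frame `key` (if present), `logPpos`, `logPneg`, `score`,
#'   `label`; attribute `nClamped` counts out-of-support values.
#' @export
nbScore <- function(model, binned) {
  n <- nrow(binned)
  lp <- rep(log(model@prior), n)
  ln <- rep(log(1 - model@prior), n)
  nClamped <- 0L
  for (f in model@features) {
    v <- binned[[f]]
    nb <- length(model@likePos[[f]])
    out <- !is.na(v) & (v < 1L | v > nb)
    if (any(out)) {
      nClamped <- nClamped + sum(out)
      v[out] <- pmin(pmax(v[out], 1L), nb)
    }
    ok <- !is.na(v)
    lp[ok] <- lp[ok] + log(model@likePos[[f]][v[ok]])
    ln[ok] <- ln[ok] + log(model@likeUnl[[f]][v[ok]])
  }
  out <- data.frame(logPpos = lp, logPneg = ln, score = lp - ln,
                    label = (lp - ln) > 0)
  if ("key" %in% names(binned)) out <- cbind(key = binned$key, out)
  attr(out, "nClamped") <- nClamped
  out
}

#' Select the prior by F1 maximization
#'
#' For each candidate `P_pos`, training examples are classified (2-voted as
#' truth positives, unlabeled as truth negatives) and the F1 score
#' computed; the argmax is returned (ties resolve to the smallest prior).
#' Only the score offset `log(P_pos / (1 - P_pos))` depends on the prior,
#' so the likelihoods are fitted once.
#'
#' @param binned discretized feature data.frame.
#' @param labels logical truth labels (positive = `TRUE`).
#' @param grid candidate priors in (0, 1).
#' @param k smoothing constant passed to [nbFit()].
#' @param scheme optional discretization scheme for [nbFit()].
#' @return list `prior`, `f1` (at the optimum), `grid` (data.frame of all
#'   candidates). If every candidate has F1 = 0, returns 0.5 with a
#'   warning.
#' @export
selectPrior <- function(binned, labels, grid = seq(0.05, 0.95, by = 0.01),
                        k = 1, scheme = NULL) {
  base <- nbFit(binned, labels, prior = 0.5, k = k, scheme = scheme)
  sc <- nbScore(base, binned)
  rel <- sc$score - log(0.5 / 0.5)  # prior-free part of the log odds
  f1s <- vapply(grid, function(p) {
    pred <- (rel + log(p / (1 - p))) > 0
    tp <- sum(pred & labels)
    if (tp == 0L) return(0)
    prec <- tp / sum(pred)
    recall <- tp / sum(labels)
    2 * prec * recall / (prec + recall)
  }, numeric(1))
  if (all(f1s == 0)) {
    warning("F1 is zero over the whole grid; defaulting to prior 0.5")
    return(list(prior = 0.5, f1 = 0, grid = data.frame(prior = grid, f1 = f1s)))
  }
  best <- which.max(f1s)  # first maximum = smallest prior
  list(prior = grid[best], f1 = f1s[best],
       grid = data.frame(prior = grid, f1 = f1s))
}

#' Peptide-level Naive-Bayes probability
#'
#' Translates each uORF (stop codon excluded), builds peptide features --
#' peptide length, the 20 amino-acid frequencies, and a mass-spectrometry
#' evidence flag -- and runs the same discretize-and-fit machinery as the
#' main score. The result is reported as a probability
#' `p_pos / (p_pos + p_neg)`, kept separate from the main uORF score. The
#' MS flag is an exact substring match of a supplied peptide within the
#' uORF translation, restricted to the portion of the uORF upstream of the
#' CDS (matches inside the CDS region are not counted as uORF evidence).
#'
#' @param catalog [UorfCatalog-class] or labeled catalog data.frame.
#' @param transcripts list of [TranscriptModel-class].
#' @param genome genome [Biostrings::DNAStringSet].
#' @param msPeptides character vector of MS-observed peptide sequences
#'   (may be empty).
#' @param labels logical positive labels (one per catalog row).
#' @param prior,k passed to [nbFit()].
#' @return data.frame `key`, `peptide`, `msEvidence`, `probability`;
#'   zero-length peptides are excluded.
#' @export
peptideScore <- function(catalog, transcripts, genome, msPeptides,
                         labels, prior = 0.5, k = 1) {
  rec <- if (is(catalog, "UorfCatalog")) uorfRecords(catalog) else catalog
  peps <- character(nrow(rec))
  prefixLen <- integer(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    tx <- transcripts[[rec$txId[i]]]
    seq <- splicedSequence(tx, genome)
    nt <- substr(seq, rec$startTx[i], rec$stopTx[i] - 1L)
    peps[i] <- as.character(Biostrings::translate(
      Biostrings::DNAString(nt), no.init.codon = TRUE))
    prefixLen[i] <- min(nchar(peps[i]),
                        max(0L, (tx@cdsStart - rec$startTx[i]) %/% 3L))
  }
  keep <- nchar(peps) > 0L
  rec <- rec[keep, , drop = FALSE]
  peps <- peps[keep]; prefixLen <- prefixLen[keep]; labels <- labels[keep]
  ms <- vapply(seq_along(peps), function(i) {
    if (!length(msPeptides)) return(FALSE)
    for (p in msPeptides) {
      m <- regexpr(p, peps[i], fixed = TRUE)
      if (m > 0 && (m + nchar(p) - 1L) <= prefixLen[i]) return(TRUE)
    }
    FALSE
  }, logical(1))
  aa <- Biostrings::AA_STANDARD
  freq <- t(vapply(peps, function(p) {
    cnt <- table(factor(strsplit(p, "")[[1]], levels = aa))
    as.numeric(cnt) / nchar(p)
  }, numeric(20)))
  fm <- data.frame(key = rec$key, pepLength = nchar(peps),
                   freq, msEvidence = ifelse(ms, "yes", "no"),
                   stringsAsFactors = FALSE)
  names(fm)[3:22] <- paste0("aa", aa)
  disc <- discretizeFeatures(fm, labels)
  model <- nbFit(disc$binned, labels, prior = prior, k = k,
                 scheme = disc$scheme)
  sc <- nbScore(model, disc$binned)
  data.frame(key = rec$key, peptide = peps, msEvidence = ms,
             probability = 1 / (1 + exp(-sc$score)),
             stringsAsFactors = FALSE)
}

# ROC curve by threshold sweep + trapezoid AUC (truth: logical)
rocCurve <- function(score, truth) {
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]
  tpr <- cumsum(truth) / sum(truth)
  fpr <- cumsum(!truth) / sum(!truth)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Leave-one-experiment-out validation
#'
#' For each fold, one profiling experiment is withheld: training positives
#' are uORFs detected in at least one (`mode = "either"`, the default) or
#' both (`mode = "both"`) of the remaining experiments; everything else --
#' including the withheld experiment's detections -- is treated as
#' unlabeled. Features are re-discretized on the fold's training labels,
#' the model refitted, and all uORFs scored. Evaluation asks how well the
#' score retrieves the withheld experiment's detections from among the
#' non-training examples: an ROC over the score sweep, with trapezoid AUC
#' (computed via \pkg{pROC}).
#'
#' @param labeled labeled catalog from [assignVotes()].
#' @param fm feature data.frame from [computeFeatures()].
#' @param mode `"either"` or `"both"`.
#' @param prior prior used for scoring (does not affect AUC).
#' @param k smoothing constant.
#' @return list with `folds` (data.frame: experiment, auc, nPos, nPool),
#'   `meanAuc`, and `roc` (per-fold ROC point data.frames). Folds with no
#'   held-out positives are skipped with a warning.
#' @export
looValidate <- function(labeled, fm, mode = c("either", "both"),
                        prior = 0.5, k = 1) {
  mode <- match.arg(mode)
  expIds <- sub("^detected\\.", "",
                grep("^detected\\.", names(labeled), value = TRUE))
  if (length(expIds) < 3L) stop("need at least 3 experiments")
  det <- as.matrix(labeled[, paste0("detected.", expIds), drop = FALSE])
  folds <- list(); rocs <- list()
  for (e in expIds) {
    others <- det[, setdiff(colnames(det), paste0("detected.", e)),
                  drop = FALSE]
    trainPos <- if (mode == "either") rowSums(others) >= 1L
                else rowSums(others) == ncol(others)
    heldOut <- det[, paste0("detected.", e)]
    pool <- !trainPos
    truth <- heldOut[pool]
    if (!any(truth)) {
      warning("fold '", e, "' has no held-out positives; skipped")
      next
    }
    disc <- discretizeFeatures(fm, trainPos)
    model <- nbFit(disc$binned, trainPos, prior = prior, k = k,
                   scheme = disc$scheme)
    sc <- nbScore(model, disc$binned)
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = as.integer(truth), predictor = sc$score[pool],
      levels = c(0, 1), direction = "<", quiet = TRUE)))
    folds[[e]] <- data.frame(experiment = e, auc = auc,
                             nPos = sum(truth), nPool = sum(pool),
                             stringsAsFactors = FALSE)
    rocs[[e]] <- rocCurve(sc$score[pool], truth)
  }
  folds <- do.call(rbind, folds)
  rownames(folds) <- NULL
  list(folds = folds, meanAuc = mean(folds$auc), roc = rocs)
}
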