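# Naive-Bayes fit/score, prior selection, peptide score, LOO validation.

binnedFrame <- function(...) data.frame(..., stringsAsFactors = FALSE)

test_that("likelihoods are smoothed bin frequencies and normalize exactly", {
  # 10 positives, 8 of them in bin 1; k = 0 -> p(bin1|pos) = 0.8
  b <- binnedFrame(f = c(rep(1L, 8), rep(2L, 2), rep(1L, 5), rep(2L, 5)))
  lab <- rep(c(TRUE, FALSE), each = 10)
  m0 <- nbFit(b, lab, k = 0.000001)  # validity requires strictly positive
  expect_equal(unname(nbLikelihoods(m0, "f")$pos["1"]), 0.8, tolerance = 1e-5)
  # unseen bin with add-one smoothing: 2 bins, n = 10 -> 1/12
  b2 <- binnedFrame(f = c(rep(1L, 10), rep(2L, 4), rep(1L, 2)))
  lab2 <- c(rep(TRUE, 10), rep(FALSE, 6))
  m1 <- nbFit(b2, lab2, k = 1)
  expect_equal(unname(nbLikelihoods(m1, "f")$pos["2"]), 1 / 12)
  # per-feature normalization and prior complement hold to 1e-9
  expect_lt(abs(sum(nbLikelihoods(m1, "f")$pos) - 1), 1e-9)
  expect_lt(abs(sum(nbLikelihoods(m1, "f")$unl) - 1), 1e-9)
  expect_equal(nbPrior(m1) + (1 - nbPrior(m1)), 1)
  # identical features get identical likelihood tables
  b3 <- binnedFrame(f1 = b2$f, f2 = b2$f)
  m3 <- nbFit(b3, lab2)
  expect_identical(nbLikelihoods(m3, "f1"), nbLikelihoods(m3, "f2"))
  # empty positive set is fatal
  expect_error(nbFit(b2, rep(FALSE, 16)), "empty")
})

test_that("hand-computed two-feature score equals log 6", {
  model <- new("NaiveBayesModel", prior = 0.5,
               likePos = list(f1 = c(`1` = 0.8, `2` = 0.2),
                              f2 = c(`1` = 0.9, `2` = 0.1)),
               likeUnl = list(f1 = c(`1` = 0.4, `2` = 0.6),
                              f2 = c(`1` = 0.3, `2` = 0.7)),
               smoothing = 0, features = c("f1", "f2"))
  sc <- nbScore(model, binnedFrame(f1 = 1L, f2 = 1L))
  expect_equal(sc$score, log(6), tolerance = 1e-12)
  expect_equal(sc$score, log(0.72 / 0.12), tolerance = 1e-12)
  expect_true(sc$label)
})

test_that("prior-only and cancellation cases behave as specified", {
  # uniform likelihoods: score = log(prior/(1-prior)); at 0.5 -> 0 -> negative
  uni <- new("NaiveBayesModel", prior = 0.5,
             likePos = list(f = c(`1` = 0.5, `2` = 0.5)),
             likeUnl = list(f = c(`1` = 0.5, `2` = 0.5)),
             smoothing = 0, features = "f")
  sc <- nbScore(uni, binnedFrame(f = 1L))
  expect_equal(sc$score, 0)
  expect_false(sc$label)  # strict > rule at the 0 threshold
  # a feature with p(A|pos) = p(A|unl) contributes nothing
  m2 <- new("NaiveBayesModel", prior = 0.6,
            likePos = list(f = c(`1` = 0.7, `2` = 0.3),
                           g = c(`1` = 0.5, `2` = 0.5)),
            likeUnl = list(f = c(`1` = 0.2, `2` = 0.8),
                           g = c(`1` = 0.5, `2` = 0.5)),
            smoothing = 0, features = c("f", "g"))
  m1 <- new("NaiveBayesModel", prior = 0.6,
            likePos = list(f = c(`1` = 0.7, `2` = 0.3)),
            likeUnl = list(f = c(`1` = 0.2, `2` = 0.8)),
            smoothing = 0, features = "f")
  expect_equal(nbScore(m2, binnedFrame(f = 1L, g = 2L))$score,
               nbScore(m1, binnedFrame(f = 1L))$score)
  # missing feature values are skipped, not penalized
  expect_equal(nbScore(m2, binnedFrame(f = 1L, g = NA_integer_))$score,
               nbScore(m1, binnedFrame(f = 1L))$score)
})

test_that("feature order does not change scores", {
  set.seed(21)
  b <- binnedFrame(a = sample(1:3, 50, TRUE), b = sample(1:2, 50, TRUE),
                   c = sample(1:4, 50, TRUE))
  lab <- rep(c(TRUE, FALSE), 25)
  m <- nbFit(b, lab)
  mRev <- nbFit(b[, c("c", "b", "a")], lab)
  expect_equal(nbScore(m, b)$score, nbScore(mRev, b[, c("c", "b", "a")])$score)
})

test_that("out-of-support bins clamp to the nearest bin and are counted", {
  b <- binnedFrame(f = c(rep(1L, 5), rep(2L, 5)))
  lab <- rep(c(TRUE, FALSE), 5)
  m <- nbFit(b, lab)
  sc <- nbScore(m, binnedFrame(f = 5L))
  expect_equal(attr(sc, "nClamped"), 1L)
  expect_equal(sc$score, nbScore(m, binnedFrame(f = 2L))$score)
})

test_that("F1-maximizing prior lands on the smallest prior of a perfect plateau", {
  # perfectly separating feature: F1 = 1 over a wide prior plateau
  b <- binnedFrame(f = c(rep(1L, 20), rep(2L, 20)))
  lab <- c(rep(TRUE, 20), rep(FALSE, 20))
  ps <- selectPrior(b, lab, grid = seq(0.1, 0.9, 0.1))
  expect_equal(ps$f1, 1)
  plateau <- ps$grid$prior[ps$grid$f1 == 1]
  expect_equal(ps$prior, min(plateau))
  # uninformative features: constant classifier; F1 maximized by calling
  # everything positive, i.e. at the large-prior end of the grid
  bu <- binnedFrame(f = rep(1L, 40))
  psu <- selectPrior(bu, lab, grid = c(0.3, 0.7))
  allPosF1 <- 2 * 0.5 * 1 / (0.5 + 1)  # precision 0.5, recall 1
  expect_equal(psu$grid$f1[psu$grid$prior == 0.7], allPosF1)
  expect_equal(psu$prior, 0.7)
})

test_that("peptide score translates uORFs and flags in-frame MS matches", {
  # uORF ATG AAA ACC TAG -> peptide MKT
  seq <- paste0("ATGAAAACCTAGCC", "ATGGATTAA")
  genome <- makeGenome(c(c1 = seq))
  txs <- list(t1 = transcriptModel("t1", "g1", "c1", "+", 1L, nchar(seq),
                                   15L, 23L))
  cat <- scanUorfs(txs, genome)
  rec <- uorfRecords(cat)
  target <- rec[rec$startTx == 1L, ]
  expect_equal(nrow(target), 1)
  lab <- rec$startTx == 1L
  ps <- peptideScore(cat, txs, genome, msPeptides = "MKT", labels = lab)
  row <- ps[ps$key == target$key, ]
  expect_equal(row$peptide, "MKT")
  expect_true(row$msEvidence)
  expect_true(all(ps$probability > 0 & ps$probability < 1))
  # identical inputs give identical probabilities
  ps2 <- peptideScore(cat, txs, genome, msPeptides = "MKT", labels = lab)
  expect_equal(ps$probability, ps2$probability)
  # no peptide library -> no MS evidence
  ps3 <- peptideScore(cat, txs, genome, msPeptides = character(0),
                      labels = lab)
  expect_false(any(ps3$msEvidence))
})

test_that("leave-one-out retrieval is perfect for separable data, null for noise", {
  n <- 1000
  makeLabeled <- function(detProb, informative) {
    active <- seq_len(n) <= 100
    lab <- data.frame(key = as.character(seq_len(n)))
    for (e in c("e1", "e2", "e3"))
      lab[[paste0("detected.", e)]] <- active & stats::runif(n) < detProb
    fm <- data.frame(key = lab$key,
                     sig = if (informative) ifelse(active, 5, 0) +
                       stats::rnorm(n, 0, 0.1) else stats::rnorm(n))
    list(lab = lab, fm = fm)
  }
  set.seed(8)
  sep <- makeLabeled(0.8, informative = TRUE)
  out <- looValidate(sep$lab, sep$fm)
  expect_gte(min(out$folds$auc), 0.95)
  # uninformative features -> AUC ~ 0.5
  nul <- makeLabeled(0.8, informative = FALSE)
  outN <- looValidate(nul$lab, nul$fm)
  expect_lt(abs(outN$meanAuc - 0.5), 0.05)
  # "both" mode trains on the intersection
  outB <- looValidate(sep$lab, sep$fm, mode = "both")
  expect_true(all(outB$folds$nPool >= out$folds$nPool))
})
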