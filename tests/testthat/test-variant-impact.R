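# Start-codon gain/loss detection, density matrices, rQTL enrichment and
# the protein-expression contrast.

# transcript with an ACG in the UTR that one substitution turns into ATG,
# plus a predicted-positive ATG uORF whose codon a variant can destroy
variantFixture <- function(strand = "+") {
  #          1       9 | 10  ACG 12 | ...        CDS 22..30
  txSeq <- paste0("ATGAAATAG", "ACGCCCTAGC", "CC", "ATGGATTAA")
  gseq <- if (strand == "+") txSeq
          else as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(txSeq)))
  genome <- makeGenome(c(c1 = gseq))
  tx <- transcriptModel("t1", "g1", "c1", strand, 1L, nchar(txSeq),
                        cdsStart = 22L, cdsEnd = 30L)
  cat <- scanUorfs(list(t1 = tx), genome)
  scored <- uorfRecords(cat)
  scored$label <- TRUE  # treat every scanned uORF as predicted positive
  list(tx = tx, genome = genome, scored = scored, txs = list(t1 = tx))
}

test_that("an ACG->ATG substitution in the UTR is a gain event", {
  fx <- variantFixture("+")
  # ACG at tx 10..12; C->T at codon position 2 (genomic 11) makes ATG
  v <- data.frame(id = "v1", contig = "c1", pos = 11L, ref = "C", alt = "T",
                  isSnv = TRUE)
  ev <- detectEvents(fx$scored, fx$txs, fx$genome, v)
  gain <- ev$events[ev$events$event == "gain", ]
  expect_equal(nrow(gain), 1)
  expect_equal(gain$refCodon, "ACG")
  expect_equal(gain$newCodon, "ATG")
  expect_equal(gain$codonPos, 2L)
})

test_that("ATG->GTG is a loss under the restricted {ATG,CTG} membership set", {
  fx <- variantFixture("+")
  v <- data.frame(id = "v2", contig = "c1", pos = 1L, ref = "A", alt = "G",
                  isSnv = TRUE)
  ev <- detectEvents(fx$scored, fx$txs, fx$genome, v,
                     lossCodons = c("ATG", "CTG"))
  loss <- ev$events[ev$events$event == "loss", ]
  expect_equal(nrow(loss), 1)
  expect_equal(loss$refCodon, "ATG")
  expect_equal(loss$newCodon, "GTG")
  # under the full 10-codon set GTG is still a member -> no loss
  ev2 <- detectEvents(fx$scored, fx$txs, fx$genome, v)
  expect_equal(nrow(ev2$events[ev2$events$event == "loss", ]), 0)
})

test_that("minus-strand variants are complemented before codon substitution", {
  fx <- variantFixture("-")
  # tx position 11 (codon ACG position 2) maps to genomic L - 11 + 1
  L <- txLength(fx$tx)
  gpos <- L - 11L + 1L
  refG <- substr(as.character(fx$genome[["c1"]]), gpos, gpos)
  expect_equal(refG, "G")  # complement of transcript C
  v <- data.frame(id = "v3", contig = "c1", pos = gpos, ref = refG,
                  alt = "A",  # genomic A -> transcript T
                  isSnv = TRUE)
  ev <- detectEvents(fx$scored, fx$txs, fx$genome, v)
  gain <- ev$events[ev$events$event == "gain", ]
  expect_equal(nrow(gain), 1)
  expect_equal(gain$newCodon, "ATG")
  expect_equal(gain$altBase, "T")
})

test_that("reference-allele mismatches are skipped and counted", {
  fx <- variantFixture("+")
  v <- data.frame(id = "bad", contig = "c1", pos = 11L, ref = "G", alt = "T",
                  isSnv = TRUE)
  ev <- detectEvents(fx$scored, fx$txs, fx$genome, v)
  expect_equal(ev$nRefMismatch, 1L)
  expect_equal(nrow(ev$events), 0)
})

test_that("density matrix conserves counts and keeps identity cells zero", {
  ev <- data.frame(refCodon = c("ACG", "ATG", "CTG"),
                   codonPos = c(2L, 1L, 1L),
                   altBase = c("T", "G", "A"))
  m <- densityMatrix(ev)
  expect_equal(sum(m), 3)
  expect_equal(m["ACG", "2:T"], 1L)
  expect_equal(dim(m), c(10L, 12L))
  # empty event list -> zero matrix
  expect_equal(sum(densityMatrix(ev[0, ])), 0)
  # identity cells: a variant cannot leave the base unchanged
  for (cdn in rownames(m)) {
    for (p in 1:3) {
      base <- substr(cdn, p, p)
      expect_equal(m[cdn, paste(p, base, sep = ":")], 0L)
    }
  }
})

test_that("rQTL enrichment ratios behave as ratios", {
  r <- rqtlEnrichment(21, 44, baseline = 0.149)
  expect_equal(r$observedPct, 48)
  expect_equal(r$fold, (21 / 44) / 0.149, tolerance = 1e-12)
  expect_equal(rqtlEnrichment(0, 10, 0.2)$fold, 0)
  expect_equal(rqtlEnrichment(2, 10, 0.2)$fold, 1)
  # duplicating every observation leaves the fold unchanged
  expect_equal(rqtlEnrichment(42, 88, 0.149)$fold, r$fold)
  expect_error(rqtlEnrichment(0, 0, 0.1), "no rQTLs")
})

test_that("annotated rQTL lists are matched to start codons before testing", {
  fx <- variantFixture("+")
  fx$scored$label <- c(TRUE, FALSE)[seq_len(nrow(fx$scored))]
  rq <- data.frame(contig = "c1", pos = c(1L, 2L, 500L))
  r <- rqtlEnrichmentFromVariants(rq, fx$scored, fx$txs, baseline = 0.5)
  expect_equal(r$nUnmatched, 1L)
})

test_that("expression contrast matches the textbook pooled t", {
  ev <- data.frame(id = c("g1", "l1"), event = c("gain", "loss"),
                   topology = c("upstream", "upstream"))
  geno <- data.frame(id = rep(c("g1", "l1"), each = 2),
                     individual = c("i1", "i2", "i3", "i4"))
  prot <- data.frame(id = rep(c("g1", "l1"), each = 2),
                     individual = c("i1", "i2", "i3", "i4"),
                     value = c(1, 2, 3, 4))
  out <- expressionContrast(ev, geno, prot, sharingThreshold = 1)
  expect_equal(out$contrast$t, -2.828, tolerance = 1e-3)
  expect_equal(out$contrast$df, 2)
  # identical groups -> t = 0
  prot2 <- prot; prot2$value <- c(1, 2, 1, 2)
  out2 <- expressionContrast(ev, geno, prot2, sharingThreshold = 1)
  expect_equal(out2$contrast$t, 0)
  # empty group after the sharing filter is an error naming the group
  expect_error(expressionContrast(ev[ev$event == "loss", ], geno, prot,
                                  sharingThreshold = 1), "gain")
})

test_that("generated gain/loss variants round-trip through the scanner", {
  study <- simulateStudy(smallConfig(seed = 4))
  rec <- uorfRecords(study$catalog)
  scored <- rec
  scored$label <- TRUE
  ev <- detectEvents(scored, study$transcripts, study$genome, study$variants)
  expect_equal(ev$nRefMismatch, 0L)
  byId <- split(ev$events, ev$events$id)
  for (j in seq_len(nrow(study$variants))) {
    v <- study$variants[j, ]
    got <- byId[[v$id]]
    tx <- NULL
    for (cand in study$transcripts)
      if (cand@contig == v$contig) { tx <- cand; break }
    tpos <- genomeToTranscript(tx, v$pos)
    altTx <- if (tx@strand == "-") chartr("ACGT", "TGCA", v$alt) else v$alt
    altSeq <- splicedSequence(tx, study$genome)
    substr(altSeq, tpos, tpos) <- altTx
    altScan <- scanTranscript(tx, altSeq)
    if (v$event == "gain") {
      # the created uORF exists on the alt sequence with an ATG/CTG start
      expect_true(!is.null(got) && any(got$event == "gain"))
      g <- got[got$event == "gain", ][1, ]
      hit <- altScan[altScan$key == g$uorfKey, ]
      expect_equal(nrow(hit), 1)
      expect_true(hit$codon %in% c("ATG", "CTG"))
    } else {
      # the lost uORF's start is no longer a member codon on the alt scan
      lostKey <- v$uorfKey
      expect_false(lostKey %in% altScan$key)
    }
  }
})

test_that("planted expression effects recover the gain-minus-loss sign", {
  study <- simulateStudy(smallConfig(seed = 5))
  out <- expressionContrast(study$variants, study$genotypes, study$protein,
                            sharingThreshold = 10)
  expect_gt(out$contrast$t, 0)  # gain raises protein, loss lowers it
})
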