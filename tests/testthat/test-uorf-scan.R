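# uORF enumeration, topology, cleansing and deduplication.

test_that("worked UTR examples yield the hand-enumerated uORFs", {
  # UTR "ATGAAATAGC" + CDS "ATGGATTAA": ATG@1 -> stop TAG@7-9 (upstream);
  # ATA@6 has no in-frame stop before CDS end -> exactly one uORF
  tx <- transcriptModel("t1", "g1", "c1", "+", 1L, 19L,
                        cdsStart = 11L, cdsEnd = 19L)
  hits <- scanTranscript(tx, "ATGAAATAGCATGGATTAA")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$startTx, 1L)
  expect_equal(hits$stopTx, 7L)
  expect_equal(hits$codon, "ATG")
  expect_equal(hits$topology, "upstream")
  expect_equal(hits$length, 9L)

  # UTR "CCATGCC" + CDS "ATGAAATAA": ATG@3 reads ATG/CCA/TGA, stop inside CDS
  tx2 <- transcriptModel("t2", "g1", "c1", "+", 1L, 16L,
                         cdsStart = 8L, cdsEnd = 16L)
  hits2 <- scanTranscript(tx2, "CCATGCCATGAAATAA")
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$startTx, 3L)
  expect_equal(hits2$stopTx, 9L)
  expect_equal(hits2$topology, "cds_overlap")

  # empty 5'UTR -> nothing to scan
  tx3 <- transcriptModel("t3", "g1", "c1", "+", 1L, 9L,
                         cdsStart = 1L, cdsEnd = 9L)
  expect_equal(nrow(scanTranscript(tx3, "ATGAAATAA")), 0)
})

test_that("in-frame start sharing the CDS stop is a shared_stop_extension", {
  # UTR "ATGCCC" + CDS "ATGAAATAA": ATG@1 in frame 0, first stop = CDS stop
  tx <- transcriptModel("t1", "g1", "c1", "+", 1L, 15L,
                        cdsStart = 7L, cdsEnd = 15L)
  hits <- scanTranscript(tx, "ATGCCCATGAAATAA")
  ext <- hits[hits$startTx == 1L, ]
  expect_equal(ext$frame, 0L)
  expect_equal(ext$topology, "shared_stop_extension")
  # direct topology classification
  expect_equal(classifyTopology(1L, 13L, 7L, 15L), "shared_stop_extension")
  expect_equal(classifyTopology(1L, 7L, 11L, 19L), "upstream")
  expect_equal(classifyTopology(3L, 9L, 8L, 16L), "cds_overlap")
})

test_that("scanner agrees with brute-force enumeration on random transcripts", {
  set.seed(101)
  for (rep in 1:60) {
    utrLen <- sample(0:300, 1)
    fix <- randomCodingTx(utrLen, nCodons = sample(10:60, 1))
    got <- scanTranscript(fix$tx, fix$seq)
    want <- bruteForceScan(fix$seq, fix$tx@cdsStart, fix$tx@cdsEnd)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got[order(got$startTx), c("startTx", "stopTx", "codon")],
                   want[order(want$startTx), ], ignore_attr = TRUE)
    }
  }
})

test_that("every emitted record satisfies the uORF invariants", {
  set.seed(7)
  for (rep in 1:20) {
    fix <- randomCodingTx(sample(30:250, 1))
    rec <- scanTranscript(fix$tx, fix$seq)
    if (!nrow(rec)) next
    expect_true(all(rec$startTx < fix$tx@cdsStart))
    expect_true(all(rec$stopTx %% 3L == rec$startTx %% 3L))
    expect_true(all(substr(fix$seq, rec$stopTx, rec$stopTx + 2L) %in%
                      c("TAA", "TAG", "TGA")))
    expect_true(all(rec$stopTx + 2L <= fix$tx@cdsEnd))
    expect_true(all((rec$topology == "shared_stop_extension") ==
                      (rec$frame == 0L & rec$stopTx + 2L == fix$tx@cdsEnd)))
  }
})

test_that("cleansing removes shared-stop extensions and aTIS starts", {
  # ATG@1 is an upstream uORF (stop TAG@7-9); ATG@10 is in frame with the
  # CDS and shares its stop codon (N-terminal extension)
  tx <- transcriptModel("t1", "g1", "c1", "+", 1L, 24L,
                        cdsStart = 16L, cdsEnd = 24L)
  seq <- "ATGAAATAGATGCCCATGGATTAA"
  genome <- makeGenome(c(c1 = seq))
  cat0 <- scanUorfs(list(t1 = tx), genome, cleanse = FALSE, dedup = FALSE)
  rec0 <- uorfRecords(cat0)
  expect_true("shared_stop_extension" %in% rec0$topology)
  cat1 <- applyCleansing(cat0)
  expect_false("shared_stop_extension" %in% uorfRecords(cat1)$topology)
  expect_gt(scanStats(cat1)$nExtensionsRemoved, 0)
  # aTIS removal by genomic start position
  atis <- data.frame(contig = "c1", pos = uorfRecords(cat1)$gStart[1],
                     strand = "+")
  cat2 <- applyCleansing(cat0, atis)
  expect_false(atis$pos %in% uorfRecords(cat2)$gStart)
  expect_equal(scanStats(cat2)$nAtisRemoved, 1L)
  # identity case: nothing to remove
  cat3 <- applyCleansing(cat1, data.frame(contig = character(0),
                                          pos = integer(0),
                                          strand = character(0)))
  expect_equal(uorfRecords(cat3)$key, uorfRecords(cat1)$key)
})

test_that("deduplication keys on genomic coordinates with smallest-id representative", {
  seq <- "ATGAAATAGCATGGATTAA"
  genome <- makeGenome(c(c1 = seq))
  txs <- list(
    b = transcriptModel("b", "g1", "c1", "+", 1L, 19L, 11L, 19L),
    a = transcriptModel("a", "g1", "c1", "+", 1L, 19L, 11L, 19L),
    c = transcriptModel("c", "g1", "c1", "+", 1L, 19L, 11L, 19L))
  cat <- scanUorfs(txs, genome, dedup = FALSE)
  expect_equal(length(cat), 3L)
  ded <- deduplicateUorfs(cat)
  expect_equal(length(ded), 1L)
  expect_equal(uorfRecords(ded)$txId, "a")
  expect_equal(scanStats(ded)$nCollapsed, 2L)
  # idempotent
  ded2 <- deduplicateUorfs(ded)
  expect_identical(uorfRecords(ded2)$key, uorfRecords(ded)$key)
})

test_that("uORFs with identical endpoints but different splicing get distinct keys", {
  # genomic layout: ATG@1; spliced transcript removes 7..18 so both
  # transcripts read a first in-frame stop whose third base is genomic 24
  gseq <- paste0("ATGAAA", "GGGGGGGGGGGG", "CCCTAG", "ATGGATTAA", "AAAA")
  genome <- makeGenome(c(c1 = gseq))
  spliced <- transcriptModel("s", "g1", "c1", "+",
                             exonStarts = c(1L, 19L),
                             exonEnds = c(6L, nchar(gseq)),
                             cdsStart = 13L, cdsEnd = 21L)
  un <- transcriptModel("u", "g1", "c1", "+", 1L, nchar(gseq),
                        cdsStart = 25L, cdsEnd = 33L)
  ks <- scanTranscript(spliced, splicedSequence(spliced, genome))
  ku <- scanTranscript(un, splicedSequence(un, genome))
  a <- ks[ks$gStart == 1L, ]; b <- ku[ku$gStart == 1L, ]
  expect_equal(a$gStop, 24L)
  expect_equal(b$gStop, 24L)
  expect_false(a$key == b$key)  # junction chain disambiguates
})
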