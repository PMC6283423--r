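# Synthetic study generator: determinism, degenerate noise regimes,
# detection-rate calibration and file-format round trips.

test_that("the generator is deterministic under a fixed seed", {
  a <- simulateStudy(smallConfig(seed = 11))
  b <- simulateStudy(smallConfig(seed = 11))
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(uorfRecords(a$catalog), uorfRecords(b$catalog))
  expect_identical(a$tis, b$tis)
  expect_identical(a$truth, b$truth)
  c <- simulateStudy(smallConfig(seed = 12))
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
})

test_that("perfect sensitivity and no noise make the 2-voted set the active set", {
  st <- simulateStudy(smallConfig(seed = 2, sensitivity = 1, fpRate = 0,
                                  tisJitterProb = 0))
  # window 0: calls sit exactly on start codons, so matching is exact
  lab <- assignVotes(st$catalog, st$tis, window = 0L)
  truth <- st$truth$uorfs
  m <- match(lab$key, truth$key)
  expect_setequal(lab$key[lab$partition == "two_voted"],
                  truth$key[truth$active])
})

test_that("zero sensitivity leaves every uORF unlabeled", {
  st <- simulateStudy(smallConfig(seed = 3, sensitivity = 0, fpRate = 0))
  lab <- suppressWarnings(assignVotes(st$catalog, st$tis))
  truth <- st$truth$uorfs
  expect_false(any(truth$detected.exp1 | truth$detected.exp2 |
                     truth$detected.exp3))
  # only lncRNA calls remain in the TIS tables; no catalog uORF is voted
  expect_true(all(lab$votes == 0))
})

test_that("per-experiment detection rates sit within 3 binomial SDs of sensitivity", {
  st <- simulateStudy(simulationConfig(seed = 6, nTranscripts = 120L))
  truth <- st$truth$uorfs
  nAct <- sum(truth$active)
  s <- st$config$sensitivity
  sd3 <- 3 * sqrt(s * (1 - s) / nAct)
  for (e in c("exp1", "exp2", "exp3")) {
    rate <- mean(truth[[paste0("detected.", e)]][truth$active])
    expect_lt(abs(rate - s), sd3)
  }
})

test_that("higher sensitivity yields more 2-voted uORFs", {
  twoVoted <- function(sens, seed) {
    st <- simulateStudy(smallConfig(seed = seed, sensitivity = sens))
    lab <- suppressWarnings(assignVotes(st$catalog, st$tis))
    sum(lab$partition == "two_voted")
  }
  lo <- mean(vapply(1:3, function(s) twoVoted(0.2, s), numeric(1)))
  hi <- mean(vapply(1:3, function(s) twoVoted(0.6, s), numeric(1)))
  expect_gt(hi, lo)
})

test_that("cross-detection fractions follow the binomial overlap expectation", {
  st <- simulateStudy(simulationConfig(seed = 9, nTranscripts = 120L))
  lab <- assignVotes(st$catalog, st$tis)
  det <- as.matrix(lab[, paste0("detected.", c("exp1", "exp2", "exp3"))])
  s <- st$config$sensitivity
  expected <- 1 - (1 - s)^2  # P(seen elsewhere | seen here), 2 other studies
  for (j in 1:3) {
    seen <- det[, j]
    cross <- rowSums(det[, -j, drop = FALSE]) > 0
    frac <- mean(cross[seen])
    expect_lt(abs(frac - expected), 0.12)
  }
})

test_that("planted uORFs are all recovered by a fresh scan", {
  st <- simulateStudy(smallConfig(seed = 13))
  rescanned <- scanUorfs(st$transcripts, st$genome, atis = st$atis)
  expect_true(all(st$truth$uorfs$key %in% uorfRecords(rescanned)$key))
})

test_that("written files load back into the same study", {
  st <- simulateStudy(smallConfig(seed = 21))
  dir <- file.path(tempdir(), "studyout")
  writeStudy(st, dir)
  genome <- loadGenome(file.path(dir, "genome.fa"))
  expect_identical(as.character(genome), as.character(st$genome))
  ann <- loadAnnotation(file.path(dir, "annotation.gtf"), genome)
  expect_equal(nrow(ann$dropped), 0)
  expect_setequal(names(ann$transcripts), names(st$transcripts))
  for (id in names(st$transcripts)) {
    expect_equal(ann$transcripts[[id]]@cdsStart, st$transcripts[[id]]@cdsStart)
    expect_equal(ann$transcripts[[id]]@strand, st$transcripts[[id]]@strand)
  }
  # catalog from loaded inputs matches the in-memory catalog
  cat2 <- scanUorfs(ann$transcripts, genome)
  expect_setequal(uorfRecords(cat2)$key, uorfRecords(st$catalog)$key)
  # TIS, conservation, expression, variants round-trip
  tis <- readTisCalls(file.path(dir, "tis_exp1.tsv"), "exp1")
  expect_equal(tis$pos, st$tis$exp1$pos)
  expect_equal(tis$reads, st$tis$exp1$reads)
  cons <- loadConservation(file.path(dir, "conservation.bedGraph"), genome)
  ctg <- names(genome)[1]
  expect_equal(cons[[ctg]], st$conservation[[ctg]], tolerance = 1e-3)
  expr <- readExpression(file.path(dir, "expression.tsv"))
  expect_equal(expr$expression, st$expression$expression, tolerance = 1e-6)
  vars <- readVariants(file.path(dir, "variants.vcf"))
  expect_equal(nrow(vars), nrow(st$variants))
  expect_setequal(paste(vars$contig, vars$pos, vars$ref, vars$alt),
                  paste(st$variants$contig, st$variants$pos,
                        st$variants$ref, st$variants$alt))
  expect_true(all(vars$isSnv))
})

test_that("degenerate recovery: perfect information gives AUC 1 and exact population", {
  st <- simulateStudy(smallConfig(seed = 30, sensitivity = 1, fpRate = 0,
                                  tisJitterProb = 0))
  truth <- st$truth$uorfs
  sets <- lapply(c("detected.exp1", "detected.exp2", "detected.exp3"),
                 function(cn) truth$key[truth[[cn]]])
  est <- schnabel(seriesFromSets(sets))
  expect_equal(est, st$truth$population)
  # a score equal to the truth ranks perfectly
  sc <- ifelse(truth$active, 1, 0) + stats::runif(nrow(truth), 0, 0.001)
  auc <- as.numeric(pROC::auc(pROC::roc(as.integer(truth$active), sc,
                                        levels = c(0, 1), direction = "<",
                                        quiet = TRUE)))
  expect_equal(auc, 1)
  # shuffled truth is a null control
  aucNull <- as.numeric(pROC::auc(pROC::roc(
    sample(as.integer(truth$active)), sc,
    levels = c(0, 1), direction = "<", quiet = TRUE)))
  expect_lt(abs(aucNull - 0.5), 0.1)
})
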