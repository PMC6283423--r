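# Self-contained synthetic study generator: a mini-genome with one
# transcript per contig, pseudo-experiment TIS calls with a controlled
# false-negative rate, conservation/expression tracks, literature and
# peptide evidence, and start-codon-interrupting variants -- all with known
# ground truth. Emulates the study conditions: few overlapping profiling
# experiments with high false-negative rates, and attribute distributions
# (conservation at start/stop codons, distance to the CDS, 5'UTR length,
# internal start-codon counts) shifted between active and inactive uORFs.

#' Simulation configuration
#'
#' Defaults define the reference study conditions: three pseudo-experiments
#' at 40% per-experiment sensitivity over a catalog of roughly 20,000
#' unique uORFs of which 5% are truly active. Activity is assigned
#' preferentially to uORFs close to the CDS, on short 5'UTRs and with few
#' internal start codons, and active start/stop codons receive elevated
#' conservation -- the qualitative attribute shifts observed in real
#' catalogs.
#'
#' @param seed integer RNG seed; the same config is byte-reproducible.
#' @param nTranscripts number of coding transcripts (one per contig).
#' @param nLnc number of non-coding (lncRNA) transcripts.
#' @param utrMeanLog,utrSdLog,utrMin,utrMax 5'UTR length distribution
#'   (log-normal, clipped), nt.
#' @param cdsCodonRange CDS length range in codons (excluding start/stop).
#' @param fractionActive fraction of unique uORFs that are truly active.
#' @param nExperiments number of pseudo-experiments.
#' @param sensitivity per-experiment probability of detecting an active
#'   uORF.
#' @param fpRate per-experiment probability of spuriously calling an
#'   inactive uORF.
#' @param conservationShift,conservationSd mean/sd of the conservation
#'   elevation added at active start/stop codons.
#' @param baselineSd sd of the baseline conservation noise.
#' @param distScale,utrScale,internalScale decay scales (nt / nt / count)
#'   of the activity-selection weights for CDS distance, UTR length and
#'   internal start count.
#' @param exprMeanLog,exprSdLog transcript expression (log-normal).
#' @param strengthMeanLog,strengthSdLog per-uORF ribosome binding strength
#'   (log-normal); detected-read counts are Poisson with mean strength x
#'   expression.
#' @param tisJitterProb probability a TIS call is reported 1 nt off.
#' @param nLiterature literature-positive uORFs (drawn from the active
#'   set).
#' @param nPeptides MS peptide sequences (substrings of active uORF
#'   translations).
#' @param nGainVariants,nLossVariants start-codon gain/loss SNVs.
#' @param nIndividuals cohort size for genotypes.
#' @param carrierMu mean carrier count per variant (negative binomial).
#' @param gainEffect,lossEffect mean protein-expression effect (SD units)
#'   among carriers of gain / loss variants.
#' @param proteinSd observation noise of protein values.
#' @param lncActiveFraction fraction of lncRNA ORFs translated.
#' @param lncReads read-count range at translated lncRNA ORF starts.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             nTranscripts = 230L,
                             nLnc = 10L,
                             utrMeanLog = log(520), utrSdLog = 0.55,
                             utrMin = 30L, utrMax = 1500L,
                             cdsCodonRange = c(100L, 300L),
                             fractionActive = 0.05,
                             nExperiments = 3L,
                             sensitivity = 0.4,
                             fpRate = 0.001,
                             conservationShift = 2, conservationSd = 0.5,
                             baselineSd = 0.5,
                             distScale = 300, utrScale = 900,
                             internalScale = 25,
                             exprMeanLog = 2, exprSdLog = 0.7,
                             strengthMeanLog = 1, strengthSdLog = 0.8,
                             tisJitterProb = 0.2,
                             nLiterature = 8L,
                             nPeptides = 12L,
                             nGainVariants = 15L,
                             nLossVariants = 60L,
                             nIndividuals = 46L,
                             carrierMu = 12,
                             gainEffect = 0.5, lossEffect = -0.5,
                             proteinSd = 1,
                             lncActiveFraction = 0.3,
                             lncReads = c(10L, 30L)) {
  cfg <- as.list(environment())
  probs <- c(cfg$fractionActive, cfg$sensitivity, cfg$fpRate,
             cfg$tisJitterProb, cfg$lncActiveFraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0,1]")
  class(cfg) <- "SimulationConfig"
  cfg
}

# random CDS of n internal codons with no in-frame stop, ATG start,
# random stop codon
randomCds <- function(nCodons) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, stopCodons())
  paste0("ATG", paste(sample(sense, nCodons, replace = TRUE), collapse = ""),
         sample(stopCodons(), 1))
}

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic study bundle
#'
#' Builds the mini-genome and annotation, scans it with [scanUorfs()] to
#' define the uORF universe, assigns true activity, and derives every
#' downstream input (TIS calls, conservation, expression, literature,
#' peptides, variants, genotypes, protein values) together with the ground
#' truth. Deterministic under the config seed.
#'
#' @param config a [simulationConfig()].
#' @return A list of class `SyntheticStudy` with elements `config`,
#'   `genome`, `transcripts`, `catalog` (the reference scan), `tis` (named
#'   list of call data.frames), `conservation`, `expression`, `literature`,
#'   `peptides`, `variants`, `genotypes`, `protein`, `atis`, and `truth`
#'   (list: `uorfs`, `population`, `variants`, `lnc`).
#' @export
simulateStudy <- function(config = simulationConfig()) {
  set.seed(config$seed)
  nc <- config$nTranscripts
  transcripts <- list()
  contigs <- character(0)

  for (i in seq_len(nc + config$nLnc)) {
    id <- sprintf("tx%04d", i)
    ctg <- sprintf("chr%04d", i)
    strand <- sample(c("+", "-"), 1)
    if (i <= nc) {
      utr5 <- round(exp(stats::rnorm(1, config$utrMeanLog, config$utrSdLog)))
      utr5 <- max(config$utrMin, min(config$utrMax, utr5))
      nCod <- sample(config$cdsCodonRange[1]:config$cdsCodonRange[2], 1)
      cds <- randomCds(nCod)
      utr3 <- sample(20:100, 1)
      txSeq <- paste0(randomSeq(utr5), cds, randomSeq(utr3))
      cdsStart <- utr5 + 1L
      cdsEnd <- utr5 + nchar(cds)
      biotype <- "coding"
    } else {
      txSeq <- randomSeq(sample(400:1200, 1))
      cdsStart <- cdsEnd <- NA_integer_
      biotype <- "lncRNA"
    }
    L <- nchar(txSeq)
    transcripts[[id]] <- transcriptModel(
      id, sprintf("gene%04d", i), ctg, strand,
      exonStarts = 1L, exonEnds = L,
      cdsStart = cdsStart, cdsEnd = cdsEnd, biotype = biotype)
    contigs[ctg] <- if (strand == "+") txSeq else revComp(txSeq)
  }
  genome <- Biostrings::DNAStringSet(contigs)

  catalog <- scanUorfs(transcripts, genome)
  rec <- uorfRecords(catalog)
  n <- nrow(rec)
  cdsStartOf <- vapply(transcripts[rec$txId], function(t) t@cdsStart, 1L)
  dist <- cdsStartOf - (rec$stopTx + 2L)
  utr <- cdsStartOf - 1L
  seqCache <- lapply(transcripts, splicedSequence, genome = genome)
  internal <- vapply(seq_len(n), function(i) {
    internalStartCount(substr(seqCache[[rec$txId[i]]], rec$startTx[i],
                              rec$stopTx[i] + 2L))
  }, integer(1))

  nActive <- round(config$fractionActive * n)
  w <- exp(-pmax(dist, 0) / config$distScale) *
    exp(-utr / config$utrScale) * exp(-internal / config$internalScale)
  activeIdx <- sample.int(n, nActive, prob = w)
  active <- rep(FALSE, n); active[activeIdx] <- TRUE

  # conservation: baseline noise, elevated at active start/stop codons
  conservation <- lapply(Biostrings::width(genome), function(wd)
    stats::rnorm(wd, 0, config$baselineSd))
  names(conservation) <- names(genome)
  for (i in activeIdx) {
    tx <- transcripts[[rec$txId[i]]]
    gpos <- transcriptToGenome(tx, c(rec$startTx[i]:(rec$startTx[i] + 2L),
                                     rec$stopTx[i]:(rec$stopTx[i] + 2L)))
    conservation[[rec$contig[i]]][gpos] <-
      conservation[[rec$contig[i]]][gpos] +
      stats::rnorm(6, config$conservationShift, config$conservationSd)
  }

  expression <- data.frame(
    txId = names(transcripts),
    expression = stats::rlnorm(length(transcripts), config$exprMeanLog,
                               config$exprSdLog),
    stringsAsFactors = FALSE)
  strength <- stats::rlnorm(n, config$strengthMeanLog, config$strengthSdLog)
  exprOf <- expression$expression[match(rec$txId, expression$txId)]

  # lncRNA ORFs and their activity
  lncTx <- Filter(function(t) is.na(t@cdsStart), transcripts)
  lncOrfs <- list()
  for (tx in lncTx) {
    seq <- seqCache[[tx@txId]]
    orfs <- enumerateOrfs(seq, startCodonSet(), nchar(seq) - 5L, nchar(seq))
    if (nrow(orfs))
      lncOrfs[[tx@txId]] <- data.frame(
        txId = tx@txId, contig = tx@contig, strand = tx@strand,
        gStart = transcriptToGenome(tx, orfs$startTx),
        startTx = orfs$startTx, stringsAsFactors = FALSE)
  }
  lncOrfs <- if (length(lncOrfs)) do.call(rbind, lncOrfs)
             else data.frame(txId = character(0), contig = character(0),
                             strand = character(0), gStart = integer(0),
                             startTx = integer(0))
  rownames(lncOrfs) <- NULL
  lncActive <- stats::runif(nrow(lncOrfs)) < config$lncActiveFraction

  # TIS calls per experiment
  expIds <- sprintf("exp%d", seq_len(config$nExperiments))
  detMat <- matrix(FALSE, n, config$nExperiments,
                   dimnames = list(NULL, expIds))
  tis <- list()
  for (e in seq_len(config$nExperiments)) {
    pDet <- ifelse(active, config$sensitivity, config$fpRate)
    det <- stats::runif(n) < pDet
    detMat[, e] <- det
    idx <- which(det)
    jitter <- ifelse(stats::runif(length(idx)) < config$tisJitterProb,
                     sample(c(-1L, 1L), length(idx), replace = TRUE), 0L)
    reads <- pmax(1, stats::rpois(length(idx), strength[idx] * exprOf[idx]))
    calls <- data.frame(contig = rec$contig[idx], pos = rec$gStart[idx] + jitter,
                        strand = rec$strand[idx], reads = reads,
                        stringsAsFactors = FALSE)
    # lncRNA ORF reads: translated ORFs get >= threshold reads when sampled
    if (nrow(lncOrfs)) {
      lDet <- lncActive & stats::runif(nrow(lncOrfs)) < config$sensitivity
      lReads <- sample(config$lncReads[1]:config$lncReads[2], sum(lDet),
                       replace = TRUE)
      # sub-threshold noise at a few inactive ORFs
      noiseIdx <- which(!lncActive & stats::runif(nrow(lncOrfs)) < 0.05)
      calls <- rbind(calls,
                     data.frame(contig = lncOrfs$contig[lDet],
                                pos = lncOrfs$gStart[lDet],
                                strand = lncOrfs$strand[lDet],
                                reads = lReads, stringsAsFactors = FALSE),
                     data.frame(contig = lncOrfs$contig[noiseIdx],
                                pos = lncOrfs$gStart[noiseIdx],
                                strand = lncOrfs$strand[noiseIdx],
                                reads = sample(1:9, length(noiseIdx),
                                               replace = TRUE),
                                stringsAsFactors = FALSE))
    }
    calls$experiment <- expIds[e]
    tis[[expIds[e]]] <- calls
  }

  # literature positives
  litIdx <- sample(activeIdx, min(config$nLiterature, nActive))
  literature <- data.frame(
    gene = vapply(transcripts[rec$txId[litIdx]], function(t) t@geneId, ""),
    contig = rec$contig[litIdx], pos = rec$gStart[litIdx],
    strand = rec$strand[litIdx], stringsAsFactors = FALSE)

  # MS peptides: substrings of active, fully-upstream uORF translations
  pepPool <- activeIdx[rec$topology[activeIdx] == "upstream" &
                         rec$length[activeIdx] >= 30L]
  peptides <- character(0)
  for (i in utils::head(pepPool[sample.int(length(pepPool))],
                        config$nPeptides)) {
    nt <- substr(seqCache[[rec$txId[i]]], rec$startTx[i], rec$stopTx[i] - 1L)
    pep <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                              no.init.codon = TRUE))
    len <- sample(5:min(9, nchar(pep)), 1)
    at <- sample(nchar(pep) - len + 1L, 1)
    peptides <- c(peptides, substr(pep, at, at + len - 1L))
  }

  variants <- simulateVariants(config, transcripts, genome, rec, activeIdx,
                               seqCache)
  genotypes <- protein <- NULL
  if (nrow(variants)) {
    glist <- plist <- list()
    individuals <- sprintf("ind%02d", seq_len(config$nIndividuals))
    for (j in seq_len(nrow(variants))) {
      k <- min(config$nIndividuals,
               1L + stats::rnbinom(1, size = 2, mu = config$carrierMu))
      carriers <- sample(individuals, k)
      eff <- if (variants$event[j] == "gain") config$gainEffect
             else config$lossEffect
      glist[[j]] <- data.frame(id = variants$id[j], individual = carriers,
                               stringsAsFactors = FALSE)
      plist[[j]] <- data.frame(id = variants$id[j], individual = carriers,
                               value = stats::rnorm(k, eff, config$proteinSd),
                               stringsAsFactors = FALSE)
    }
    genotypes <- do.call(rbind, glist)
    protein <- do.call(rbind, plist)
  }

  truth <- list(
    uorfs = data.frame(key = rec$key, active = active,
                       stats::setNames(as.data.frame(detMat),
                                       paste0("detected.", expIds)),
                       stringsAsFactors = FALSE),
    population = nActive,
    variants = variants[, c("id", "event")],
    lnc = data.frame(txId = lncOrfs$txId, gStart = lncOrfs$gStart,
                     active = lncActive, stringsAsFactors = FALSE))

  structure(list(config = config, genome = genome, transcripts = transcripts,
                 catalog = catalog, tis = tis, conservation = conservation,
                 expression = expression, literature = literature,
                 peptides = peptides, variants = variants,
                 genotypes = genotypes, protein = protein,
                 atis = data.frame(contig = character(0), pos = integer(0),
                                   strand = character(0)),
                 truth = truth),
            class = "SyntheticStudy")
}

# start-codon gain and loss SNVs with guaranteed round-trip behaviour
simulateVariants <- function(config, transcripts, genome, rec, activeIdx,
                             seqCache) {
  rows <- list()
  bases <- c("A", "C", "G", "T")
  # loss: break the start codon of an active uORF out of the codon set
  lossPool <- sample(activeIdx)
  taken <- 0L
  for (i in lossPool) {
    if (taken >= config$nLossVariants) break
    tx <- transcripts[[rec$txId[i]]]
    cp <- sample(1:3, 1)
    refCodon <- rec$codon[i]
    cands <- setdiff(bases, substr(refCodon, cp, cp))
    cands <- cands[vapply(cands, function(b) {
      cdn <- refCodon; substr(cdn, cp, cp) <- b
      !cdn %in% startCodonSet()
    }, logical(1))]
    if (!length(cands)) next
    altTx <- cands[sample.int(length(cands), 1)]
    gpos <- transcriptToGenome(tx, rec$startTx[i] + cp - 1L)
    refG <- substr(as.character(genome[[tx@contig]]), gpos, gpos)
    altG <- if (tx@strand == "-") complementBase(altTx) else altTx
    taken <- taken + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("loss%03d", taken), contig = tx@contig, pos = gpos,
      ref = refG, alt = altG, event = "loss", uorfKey = rec$key[i],
      topology = rec$topology[i], stringsAsFactors = FALSE)
  }
  # gain: single substitutions in UTRs creating a complete ATG/CTG uORF
  taken <- 0L
  for (id in sample(names(transcripts))) {
    if (taken >= config$nGainVariants) break
    tx <- transcripts[[id]]
    if (is.na(tx@cdsStart) || tx@cdsStart < 10L) next
    seq <- seqCache[[id]]
    tm <- threemers(substr(seq, 1L, tx@cdsStart - 1L))
    found <- FALSE
    for (q in sample(seq_len(max(0L, tx@cdsStart - 3L)))) {
      if (found) break
      cdn <- tm[q]
      if (cdn %in% startCodonSet()) next
      for (target in c("ATG", "CTG")) {
        diffPos <- which(strsplit(cdn, "")[[1]] != strsplit(target, "")[[1]])
        if (length(diffPos) != 1L) next
        # the would-be uORF needs a complete stop before the CDS end
        altSeq <- seq
        substr(altSeq, q + diffPos - 1L, q + diffPos - 1L) <-
          substr(target, diffPos, diffPos)
        hit <- enumerateOrfs(altSeq, target, startMax = tx@cdsStart - 3L,
                             stopMax = tx@cdsEnd)
        hit <- hit[hit$startTx == q, , drop = FALSE]
        if (!nrow(hit)) next
        if (classifyTopology(q, hit$stopTx[1], tx@cdsStart, tx@cdsEnd) ==
            "shared_stop_extension") next
        tpos <- q + diffPos - 1L
        gpos <- transcriptToGenome(tx, tpos)
        refG <- substr(as.character(genome[[tx@contig]]), gpos, gpos)
        altTx <- substr(target, diffPos, diffPos)
        altG <- if (tx@strand == "-") complementBase(altTx) else altTx
        taken <- taken + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("gain%03d", taken), contig = tx@contig, pos = gpos,
          ref = refG, alt = altG, event = "gain", uorfKey = NA_character_,
          topology = NA_character_, stringsAsFactors = FALSE)
        found <- TRUE
        break
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(id = character(0), contig = character(0),
                        pos = integer(0), ref = character(0),
                        alt = character(0), event = character(0),
                        uorfKey = character(0), topology = character(0),
                        stringsAsFactors = FALSE)
  df$isSnv <- rep(TRUE, nrow(df))
  df
}

#' Write a synthetic study to standard-format files
#'
#' FASTA genome and peptides, GTF annotation, bedGraph conservation,
#' VCF variants, and TSV tables for TIS calls, expression, literature,
#' aTIS, genotypes and protein values.
#'
#' @param study a `SyntheticStudy` from [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  p <- function(f) file.path(dir, f)

  Biostrings::writeXStringSet(study$genome, p("genome.fa"))
  paths$genome <- p("genome.fa")

  grs <- lapply(study$transcripts, function(tx) {
    ex <- GenomicRanges::GRanges(tx@contig,
                                 IRanges::IRanges(min(tx@exonStarts),
                                                  max(tx@exonEnds)),
                                 strand = tx@strand)
    ex$type <- "exon"
    rngs <- ex
    if (!is.na(tx@cdsStart)) {
      g1 <- transcriptToGenome(tx, tx@cdsStart)
      g2 <- transcriptToGenome(tx, tx@cdsEnd)
      cds <- GenomicRanges::GRanges(tx@contig,
                                    IRanges::IRanges(min(g1, g2), max(g1, g2)),
                                    strand = tx@strand)
      cds$type <- "CDS"
      cds$phase <- 0L  # single CDS range, starts in frame
      ex$phase <- NA_integer_
      rngs <- c(ex, cds)
    }
    rngs$transcript_id <- tx@txId
    rngs$gene_id <- tx@geneId
    rngs$transcript_biotype <- if (tx@biotype == "coding") "protein_coding"
                               else "lncRNA"
    rngs
  })
  gtf <- suppressWarnings(do.call(c, unname(grs)))
  rtracklayer::export(gtf, p("annotation.gtf"), format = "gtf")
  paths$annotation <- p("annotation.gtf")

  for (e in names(study$tis)) {
    f <- p(sprintf("tis_%s.tsv", e))
    utils::write.table(
      data.frame(contig = study$tis[[e]]$contig,
                 start = study$tis[[e]]$pos - 1L,
                 strand = study$tis[[e]]$strand,
                 reads = study$tis[[e]]$reads),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[paste0("tis_", e)]] <- f
  }

  consGr <- suppressWarnings(do.call(c, lapply(names(study$conservation),
                                               function(ctg) {
    v <- round(study$conservation[[ctg]], 4)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    GenomicRanges::GRanges(ctg, IRanges::IRanges(ends - r$lengths + 1L, ends),
                           score = r$values)
  })))
  rtracklayer::export(consGr, p("conservation.bedGraph"), format = "bedGraph")
  paths$conservation <- p("conservation.bedGraph")

  utils::write.table(study$expression, p("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$literature, p("literature.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$atis, p("atis.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(study$peptides)) {
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(stats::setNames(
        study$peptides, sprintf("pep%03d", seq_along(study$peptides)))),
      p("peptides.fa"))
    paths$peptides <- p("peptides.fa")
  }
  writeVcfFile(study$variants, study$genome, p("variants.vcf"))
  paths$variants <- p("variants.vcf")
  if (!is.null(study$genotypes))
    utils::write.table(study$genotypes, p("genotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(study$protein))
    utils::write.table(study$protein, p("protein.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  paths$expression <- p("expression.tsv")
  invisible(paths)
}

# minimal VCF v4.2 emitter (CHROM/POS/ID/REF/ALT only); read back with
# readVariants()
writeVcfFile <- function(variants, genome, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (ctg in names(genome))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ctg,
                       Biostrings::width(genome)[match(ctg, names(genome))]),
               con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(variants)) {
    ord <- order(variants$contig, variants$pos)
    v <- variants[ord, , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", v$contig, v$pos,
                       v$id, v$ref, v$alt), con)
  }
  invisible(file)
}

#' Run the full classification pipeline on a synthetic study
#'
#' Scan, vote assignment, feature computation, discretization and
#' Naive-Bayes fit on the 2-voted positives, scoring, leave-one-out
#' validation, and mark-recapture population estimation.
#'
#' @param study a `SyntheticStudy` (or equivalent list of loaded inputs).
#' @param selectPriorGrid grid for [selectPrior()]; `NULL` fits with
#'   prior 0.5.
#' @param looMode passed to [looValidate()].
#' @return list `catalog`, `labeled`, `features`, `ksRanking`, `model`,
#'   `scores`, `loo`, `population` (list: `series`, `schnabel`,
#'   `schumacherEschmeyer`, `allOrders`).
#' @export
runPipeline <- function(study, selectPriorGrid = seq(0.05, 0.95, 0.05),
                        looMode = "either") {
  catalog <- scanUorfs(study$transcripts, study$genome, atis = study$atis)
  labeled <- assignVotes(catalog, study$tis, study$literature)
  fm <- computeFeatures(labeled, study$transcripts, study$genome,
                        conservation = study$conservation,
                        expression = study$expression)
  posLab <- labeled$partition == "two_voted"
  disc <- discretizeFeatures(fm, posLab)
  ks <- ksRank(fm, posLab)
  prior <- 0.5
  if (!is.null(selectPriorGrid))
    prior <- selectPrior(disc$binned, posLab, grid = selectPriorGrid,
                         scheme = disc$scheme)$prior
  model <- nbFit(disc$binned, posLab, prior = prior, scheme = disc$scheme)
  scores <- nbScore(model, disc$binned)
  loo <- looValidate(labeled, fm, mode = looMode)
  expIds <- sub("^detected\\.", "",
                grep("^detected\\.", names(labeled), value = TRUE))
  sets <- lapply(expIds, function(e)
    labeled$key[labeled[[paste0("detected.", e)]]])
  names(sets) <- expIds
  series <- seriesFromSets(sets)
  population <- list(
    series = series,
    schnabel = schnabel(series),
    schumacherEschmeyer = schumacherEschmeyer(series),
    allOrders = estimateAllOrders(sets))
  list(catalog = catalog, labeled = labeled, features = fm, ksRanking = ks,
       model = model, scores = scores, loo = loo, population = population)
}

#' Recovery metrics of a pipeline run against ground truth
#'
#' @param study the `SyntheticStudy` that produced the inputs.
#' @param pipeline result of [runPipeline()] on that study.
#' @return list `aucVsTruth` (score vs true activity), `populationEstimate`,
#'   `populationErrorPct`, `topFeatures` (top 5 by KS),
#'   `shiftedFeaturesInTop5` (are conservation-at-start and CDS distance
#'   both in the top 5), `meanLooAuc`.
#' @export
recoveryReport <- function(study, pipeline) {
  truth <- study$truth$uorfs
  m <- match(pipeline$labeled$key, truth$key)
  act <- truth$active[m]
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = as.integer(act), predictor = pipeline$scores$score,
    levels = c(0, 1), direction = "<", quiet = TRUE)))
  est <- pipeline$population$schnabel
  top5 <- utils::head(pipeline$ksRanking$feature, 5)
  list(aucVsTruth = auc,
       populationEstimate = est,
       populationErrorPct = 100 * (est - study$truth$population) /
         study$truth$population,
       topFeatures = top5,
       shiftedFeaturesInTop5 = all(c("consStart", "distToCds") %in% top5),
       meanLooAuc = pipeline$loo$meanAuc)
}
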