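# uORFcatalog

Genome-wide cataloguing and classification of upstream open reading
frames (uORFs) in R.

A uORF is a start codon in a transcript's 5' untranslated region with an
in-frame stop codon ending at or before the end of the main coding
sequence (CDS). Translated uORFs regulate translation of the downstream
gene, and variants that create or destroy a uORF start codon can shift
protein levels. Ribosome-profiling experiments identify translated start
codons but miss many active uORFs in any single experiment, so the set of
confirmed positives is small and there are no confirmed negatives. This
package is for computational biologists who want to go from a genome +
annotation + per-experiment translation-initiation-site (TIS) calls to a
scored, ranked catalog of likely-active uORFs, an estimate of how many
active uORFs exist in total, and an annotation of start-codon gain/loss
variants.

## The method in brief

* **Scan**: every position in a 5'UTR whose 3-mer is ATG or a
  near-cognate (TTG, GTG, CTG, AAG, AGG, ACG, ATA, ATT, ATC) and whose
  *first* in-frame stop codon ends at or before the CDS end is one uORF;
  N-terminal extensions (shared CDS stop) and annotated alternative
  initiation sites are removed, and uORFs are deduplicated by genomic
  coordinates.
* **Label**: uORFs detected (±1 nt) in ≥2 experiments or sources are
  `two_voted` positives; exactly one source, `one_voted`; otherwise
  `unlabeled`.
* **Classify** (positive–unlabeled Naive Bayes): attributes are
  discretized by the Fayyad–Irani MDLP criterion and ranked by the
  two-sample KS statistic; with add-one-smoothed bin likelihoods the
  score is the natural-log odds

  ```
  score = log( P_pos * prod_i p(A_i|pos)  /  (1-P_pos) * prod_i p(A_i|unl) )
  ```

  with `score > 0` a positive call and `P_pos` chosen by F1
  maximization. Validation is leave-one-experiment-out ROC/AUC.
* **Estimate the population** by mark-recapture over experiments:
  Petersen `N = CM/R`, Schnabel `N = sum(C_t M_t)/sum(R_t)`, and
  Schumacher–Eschmeyer `N = sum(C_t M_t^2)/sum(R_t M_t)`, with a solver
  that recovers pairwise set overlaps from published aggregate counts.
* **Variant impact**: strand-aware detection of start-codon loss (SNV
  destroys membership of a predicted-positive start) and gain (SNV
  creates a complete new ATG/CTG uORF), density matrices of reference
  codon × interrupting variant, rQTL enrichment, and a pooled-t protein
  expression contrast between gain and loss carriers.

A synthetic-study generator (`simulateStudy()`) produces a mini-genome,
annotation, TIS calls with controlled false-negative rates, conservation
and expression tracks, peptides, variants, genotypes and protein values —
with full ground truth — so the entire pipeline runs and is tested
without any downloads.

## Worked example

```r
library(uORFcatalog)

study   <- simulateStudy(simulationConfig(seed = 1))
catalog <- scanUorfs(study$transcripts, study$genome)
catalog
#> UorfCatalog with 20070 uORF record(s)
#>   topology: cds_overlap=1486 upstream=18584
#>   top codons: ATT=2047 ATG=2032 GTG=2030 ATA=2025
#>   stats: nScanned=20795 nExtensionsRemoved=725 nAtisRemoved=0 nCollapsed=0

labeled <- assignVotes(catalog, study$tis, study$literature)
table(labeled$partition)
#> one_voted two_voted unlabeled
#>       538       371     19161

fm <- computeFeatures(labeled, study$transcripts, study$genome,
                      conservation = study$conservation,
                      expression = study$expression)
head(ksRank(fm, labeled$partition == "two_voted"), 5)
#>      feature        ks rank
#> 1  consStart 0.9400379    1
#> 2   consStop 0.7156576    2
#> 3 nUorfsOnTx 0.3233359    3
#> 4  utrLength 0.3138661    4
#> 5  distToCds 0.3008577    5

loo <- looValidate(labeled, fm)
loo$folds
#>   experiment       auc nPos nPool
#> 1       exp1 0.9410129  184 19347
#> 2       exp2 0.9346479  178 19341
#> 3       exp3 0.9347429  176 19339
```

Reading this: the scan found 20,070 unique uORFs after removing 725
N-terminal extensions; three pseudo-experiments at 40% sensitivity
labelled 371 uORFs as 2-voted positives; conservation at the start/stop
codons and position relative to the CDS are the most discriminative
attributes by KS; and a model trained on any two experiments retrieves
the withheld third with AUC ≈ 0.94. The mark-recapture machinery turns
the same detection sets into a population estimate:

```r
sets <- lapply(c("exp1", "exp2", "exp3"),
               function(e) labeled$key[labeled[[paste0("detected.", e)]]])
schnabel(seriesFromSets(sets))
#> 1180          # true planted population: 1004
```

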