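Package: uORFcatalog
Title: Genome-Wide Cataloguing and Classification of Upstream Open Reading Frames
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scans annotated 5' untranslated regions for upstream open
    reading frames (uORFs) initiating at ATG and near-cognate start codons,
    labels them with translation-initiation-site calls from ribosome
    profiling experiments, and classifies the full catalog with a
    positive-unlabeled Naive-Bayes model over MDLP-discretized sequence,
    position and conservation attributes. Also estimates the total active
    uORF population by mark-recapture (Petersen, Schnabel,
    Schumacher-Eschmeyer) from overlapping experiment detections, and
    annotates variants that create or destroy uORF start codons, including
    density matrices, rQTL enrichment and protein-expression contrasts. A
    self-contained synthetic-study generator produces genome, annotation,
    pseudo-experiment TIS calls, tracks and variants with known ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR,
    pROC
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Sequencing, Annotation, Classification, RiboSeq, GenePrediction
RoxygenNote: 7.3.3
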