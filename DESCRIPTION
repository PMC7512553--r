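Package: tpscan
Title: Transcriptional Peak Discovery and Consensus Differential
    Expression for Small RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and analysis of candidate small-RNA loci
    ("transcriptional peaks") from strand-aware short-read alignments.
    Builds strand-specific per-base coverage from pooled libraries,
    segments it into peaks (depth strictly greater than a threshold),
    filters peaks by length and mean coverage, classifies each peak by
    genomic context against a reference annotation (known, partially
    novel nested/overlapping, novel intergenic; sense/antisense), counts
    reads per peak, and calls differential expression with a simplified
    two-estimator negative-binomial consensus rule (Wald test on
    median-of-ratios-normalized counts plus a conditional exact test on
    TMM-equalized pseudo-counts). Set logic across pathogen x generation
    contrasts isolates universally responsive loci, and a seed
    complementarity plus nearest-neighbor hybridization-energy scanner
    screens miRNA targets. A first-class synthetic-data module generates
    genomes, annotations, planted loci, alignments and count matrices
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    edgeR,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, SmallRNA, DifferentialExpression, Coverage,
    PeakDetection, Annotation
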