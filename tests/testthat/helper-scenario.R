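## The default synthetic study, computed once per test run and shared by the
## tests that exercise the full pipeline.

.scenarioCache <- new.env(parent = emptyenv())

defaultScenario <- function(seed = 1L) {
    key <- paste0("seed", seed)
    if (!is.null(.scenarioCache[[key]])) return(.scenarioCache[[key]])
    design <- StudyDesign(seed = as.integer(seed))
    ga <- simulateGenomeAnnotation(1L, 50000L, seed = seed)
    loci <- simulatePlantedLoci(ga$annotation, design)
    aln <- simulateAlignments(loci, design)
    tps <- callPeaks(aln)
    cls <- classifyTps(tps, ga$annotation)
    cnt <- lapply(aln, function(g) countReads(tps, g))
    se <- assembleCountMatrix(cnt, sampleSheet(design), features = tps)
    de <- runConsensusDE(se, design)
    ov <- GenomicRanges::findOverlaps(tps, loci, type = "equal")
    tp2locus <- setNames(
        S4Vectors::mcols(loci)$locus_id[S4Vectors::subjectHits(ov)],
        S4Vectors::mcols(tps)$tp_id[S4Vectors::queryHits(ov)])
    sc <- list(design = design, genome = ga$genome,
               annotation = ga$annotation, loci = loci, aln = aln,
               tps = tps, cls = cls, counts = cnt, se = se, de = de,
               tp2locus = tp2locus)
    .scenarioCache[[key]] <- sc
    sc
}
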