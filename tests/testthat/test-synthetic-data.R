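test_that("genome/annotation generator is deterministic and seed-sensitive", {
    a <- simulateGenomeAnnotation(2, 20000, seed = 7)
    b <- simulateGenomeAnnotation(2, 20000, seed = 7)
    expect_identical(as.character(a$genome), as.character(b$genome))
    expect_identical(as.data.frame(a$annotation), as.data.frame(b$annotation))
    c <- simulateGenomeAnnotation(1, 50000, seed = 7)
    d <- simulateGenomeAnnotation(1, 50000, seed = 8)
    expect_false(identical(as.data.frame(c$annotation),
                           as.data.frame(d$annotation)))
})

test_that("generated annotation contains the required feature mix and gaps", {
    ga <- simulateGenomeAnnotation(1, 50000, seed = 7)
    bt <- S4Vectors::mcols(ga$annotation)$biotype
    for (need in c("miRNA", "pre_miRNA", "rRNA", "coding_exon", "intron",
                   "five_prime_UTR", "three_prime_UTR"))
        expect_true(need %in% bt, label = paste("biotype", need, "present"))
    # at least one annotation-free gap of >= 1000 nt
    ir <- IRanges::reduce(IRanges::IRanges(GenomicRanges::start(ga$annotation),
                                           GenomicRanges::end(ga$annotation)))
    gaps <- IRanges::gaps(ir, start = 1L, end = 50000L)
    expect_true(any(IRanges::width(gaps) >= 1000))
    expect_error(simulateGenomeAnnotation(1, 5000, seed = 1), "too small")
})

test_that("planted truth classes agree with brute-force intersection", {
    sc <- defaultScenario()
    ann <- as.data.frame(sc$annotation)
    for (i in seq_along(sc$loci)) {
        l <- sc$loci[i]
        cls <- S4Vectors::mcols(l)$truth_class
        ovw <- pmax(0L, pmin(ann$end, GenomicRanges::end(l)) -
                        pmax(ann$start, GenomicRanges::start(l)) + 1L)
        if (cls == "novel") {
            expect_true(all(ovw == 0L), label = paste(
                S4Vectors::mcols(l)$locus_id, "is annotation-free"))
        } else if (cls == "known") {
            exact <- any(ovw > 0 & ann$start == GenomicRanges::start(l) &
                         ann$end == GenomicRanges::end(l) &
                         ann$strand == as.character(GenomicRanges::strand(l)) &
                         ann$biotype %in% srnaBiotypes())
            expect_true(exact, label = paste(
                S4Vectors::mcols(l)$locus_id, "coincides with annotated sRNA"))
        } else if (cls == "nested") {
            expect_true(any(ann$start <= GenomicRanges::start(l) &
                            ann$end >= GenomicRanges::end(l)))
        } else {  # overlapping
            expect_true(any(ovw > 0))
            expect_false(any(ann$start <= GenomicRanges::start(l) &
                             ann$end >= GenomicRanges::end(l)))
        }
    }
})

test_that("simulated alignments respect coverage targets and background cap", {
    sc <- defaultScenario()
    loci <- sc$loci
    m <- S4Vectors::mcols(loci)
    pooled <- unlist(GenomicRanges::GRangesList(lapply(sc$aln, GenomicRanges::granges)))
    # per-locus pooled realized coverage via the brute-force pileup oracle
    design <- sc$design
    sheet <- sampleSheet(design)
    for (i in seq_along(loci)) {
        onCtg <- pooled[as.character(GenomicRanges::seqnames(pooled)) ==
                        as.character(GenomicRanges::seqnames(loci[i])) &
                        as.character(GenomicRanges::strand(pooled)) ==
                        as.character(GenomicRanges::strand(loci[i]))]
        depth <- oraclePileup(GenomicRanges::start(onCtg),
                              GenomicRanges::end(onCtg), 50000L)
        span <- GenomicRanges::start(loci[i]):GenomicRanges::end(loci[i])
        realized <- mean(depth[span])
        tgt <- m$target_mean_coverage[i]
        if (tgt == 0) {
            expect_identical(sum(depth[span]), 0L)
        } else if (tgt >= 20 && IRanges::width(loci[i]) >= 22) {
            # design multiplier: mean per-library effect
            ctrl <- sheet$bacterium == controlBacterium(design)
            cid <- sprintf("%s_%s", sheet$bacterium, sheet$generation)
            mult <- ifelse(ctrl, 1, 2^m$log2fc[i, ][cid])
            mult[is.na(mult)] <- 1
            expected <- tgt * mean(mult)
            expect_lt(abs(realized - expected) / expected, 0.20,
                      label = paste(m$locus_id[i], "coverage calibration"))
        } else if (m$locus_id[i] == "novel_low_cov") {
            expect_lt(realized, 10)
        }
    }
    # background regions (away from loci) pooled depth <= 2
    depthAll <- oraclePileup(GenomicRanges::start(pooled),
                             GenomicRanges::end(pooled), 50000L)
    lociMask <- rep(FALSE, 50000L)
    for (i in seq_along(loci)) {
        lo <- max(1L, GenomicRanges::start(loci)[i] - 250L)
        hi <- min(50000L, GenomicRanges::end(loci)[i] + 250L)
        lociMask[lo:hi] <- TRUE
    }
    expect_lte(max(depthAll[!lociMask]), 2L)
})

test_that("alignment simulation rejects out-of-bounds loci and is deterministic", {
    design <- StudyDesign(seed = 3L)
    ga <- simulateGenomeAnnotation(1, 50000, seed = 3)
    loci <- simulatePlantedLoci(ga$annotation, design)
    bad <- loci
    suppressWarnings(GenomicRanges::ranges(bad)[1] <-
                         IRanges::IRanges(49990, 50020))
    expect_error(simulateAlignments(bad, design), "outside contig")
    a1 <- simulateAlignments(loci, design)
    a2 <- simulateAlignments(loci, design)
    expect_identical(lapply(a1, as.data.frame), lapply(a2, as.data.frame))
})

test_that("count simulator hits its planted means, ratios, and determinism", {
    design <- StudyDesign(seed = 5L)
    ids <- sprintf("f%05d", 1:10000)
    cm <- simulateCounts(ids, design, baselineMean = 100, dispersion = 0,
                         seed = 11L)
    sheet <- sampleSheet(design)
    for (b in c("OP50", "PAO1")) {
        cols <- sheet$sample_id[sheet$bacterium == b & sheet$generation == "F1"]
        m <- mean(cm[, cols])
        se <- sqrt(100 / (10000 * length(cols)))
        expect_lt(abs(m - 100), 3 * se)
    }
    # planted +2 in all four contrasts: pathogen/control ratio ~ 4
    lfc <- matrix(0, 100, 4,
                  dimnames = list(NULL, designContrasts(design)$contrast_id))
    lfc[1, ] <- 2
    cm2 <- simulateCounts(sprintf("g%03d", 1:100), design,
                          baselineMean = 1000, dispersion = 0, log2fc = lfc,
                          seed = 13L)
    ctrl <- sheet$sample_id[sheet$bacterium == "OP50"]
    path <- sheet$sample_id[sheet$bacterium != "OP50"]
    expect_lt(abs(mean(cm2[1, path]) / mean(cm2[1, ctrl]) - 4), 0.2)
    expect_identical(cm2, simulateCounts(sprintf("g%03d", 1:100), design,
                                         baselineMean = 1000, dispersion = 0,
                                         log2fc = lfc, seed = 13L))
    expect_error(simulateCounts(ids, design, baselineMean = -1), "positive")
    expect_error(simulateCounts(ids, design, dispersion = -0.1), ">= 0")
})

test_that("study design exposes the four pathogen contrasts and sheet", {
    design <- StudyDesign()
    contr <- designContrasts(design)
    expect_identical(sort(contr$contrast_id),
                     sort(c("PAO1_F1", "PAO1_F2", "MST1_F1", "MST1_F2")))
    expect_identical(nrow(sampleSheet(design)), 18L)
    expect_error(StudyDesign(replicates = 1L), "replicates")
})
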