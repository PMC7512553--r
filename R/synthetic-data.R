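## Synthetic inputs with known ground truth: toy genome + annotation, planted
## sRNA loci, read alignments that tile them, and NB count matrices with
## planted fold changes.  Everything is a pure function of its seed.

.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(as.integer(seed) %% .Machine$integer.max)
    expr
}

.randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a toy genome and annotation
#'
#' Generates random contig sequences and a feature annotation laid out so
#' that every genomic context the peak classifier distinguishes is present:
#' miRNA hairpins (pre-miRNA with a nested mature miRNA), an rRNA gene,
#' coding genes with 5'UTR/exon/intron/3'UTR sub-features, assorted small
#' ncRNAs (tRNA, 21ur piRNA, snoRNA, lincRNA, pseudogene), and guaranteed
#' intergenic gaps of at least 1,000 nt between blocks.  Output is
#' deterministic for a fixed seed.
#'
#' @param nContigs integer >= 1; number of contigs.
#' @param contigLength integer >= 10000; length of each contig in nt.
#' @param seed integer RNG seed.
#' @return list with elements `genome` (a [Biostrings::DNAStringSet]) and
#'   `annotation` (a [GenomicRanges::GRanges] with metadata columns
#'   `feature_id`, `biotype`, `parent_id`; seqlengths set).
#' @examples
#' ga <- simulateGenomeAnnotation(1, 50000, seed = 7)
#' table(S4Vectors::mcols(ga$annotation)$biotype)
#' @export
simulateGenomeAnnotation <- function(nContigs = 1L, contigLength = 50000L,
                                     seed = 1L) {
    stopifnot(nContigs >= 1L)
    if (contigLength < 10000L)
        stop("contigLength too small to host the required feature mix ",
             "(need >= 10000 nt)")
    .withSeed(seed, {
        feats <- list()
        seqs <- character(nContigs)
        for (ci in seq_len(nContigs)) {
            ctg <- sprintf("ctg%d", ci)
            seqs[ci] <- .randomDna(contigLength)
            feats[[ci]] <- .layoutContig(ctg, contigLength, ci)
        }
        ann <- suppressWarnings(do.call(c, feats))  # contigs share no seqlevels yet
        genome <- DNAStringSet(seqs)
        names(genome) <- sprintf("ctg%d", seq_len(nContigs))
        seqlevels(ann) <- names(genome)
        seqlengths(ann) <- width(genome)
        list(genome = genome, annotation = ann)
    })
}

## Lay features along one contig: a required block set first (pre-miRNA,
## coding gene, rRNA), then optional blocks while space remains, each block
## followed by a >= 1000 nt gap.
.layoutContig <- function(ctg, contigLength, contigIndex) {
    gap <- function() sample(1000:1600, 1L)
    rstrand <- function() sample(c("+", "-"), 1L)
    rows <- list()
    k <- 0L
    addRow <- function(start, end, strand, biotype, fid, parent = NA_character_) {
        k <<- k + 1L
        rows[[k]] <<- data.frame(start = start, end = end, strand = strand,
                                 biotype = biotype, feature_id = fid,
                                 parent_id = parent, stringsAsFactors = FALSE)
    }
    counters <- new.env()
    nextId <- function(prefix) {
        n <- (get0(prefix, envir = counters, ifnotfound = 0L)) + 1L
        assign(prefix, n, envir = counters)
        sprintf("%s_%s_%d", prefix, ctg, n)
    }
    blockMirna <- function(at) {
        w <- sample(60:90, 1L); s <- rstrand()
        pid <- nextId("premir")
        addRow(at, at + w - 1L, s, "pre_miRNA", pid)
        moff <- sample(5:(w - 26L), 1L)
        addRow(at + moff, at + moff + 21L, s, "miRNA", nextId("mir"), pid)
        w
    }
    blockCoding <- function(at) {
        s <- rstrand()
        gid <- nextId("gene")
        widths <- c(utr5 = sample(100:150, 1L), exon1 = sample(200:300, 1L),
                    intron = sample(100:300, 1L), exon2 = sample(200:300, 1L),
                    utr3 = sample(100:200, 1L))
        bts <- c("five_prime_UTR", "coding_exon", "intron", "coding_exon",
                 "three_prime_UTR")
        if (s == "-") { widths <- rev(widths); bts <- rev(bts) }
        pos <- at
        for (j in seq_along(widths)) {
            addRow(pos, pos + widths[j] - 1L, s, bts[j],
                   sprintf("%s_part%d", gid, j), gid)
            pos <- pos + widths[j]
        }
        sum(widths)
    }
    blockSimple <- function(biotype, wlo, whi, prefix) {
        force(biotype); force(wlo); force(whi); force(prefix)
        function(at) {
            w <- if (wlo == whi) wlo else sample(wlo:whi, 1L)
            addRow(at, at + w - 1L, rstrand(), biotype, nextId(prefix))
            w
        }
    }
    required <- list(blockMirna, blockCoding,
                     blockSimple("rRNA", 800L, 1200L, "rrn"))
    optional <- list(blockMirna,
                     blockSimple("tRNA", 70L, 70L, "trna"),
                     blockSimple("piRNA_21ur", 21L, 21L, "p21ur"),
                     blockSimple("snoRNA", 90L, 90L, "sno"),
                     blockCoding,
                     blockSimple("lincRNA", 300L, 600L, "linc"),
                     blockSimple("pseudogene", 400L, 400L, "pseudo"),
                     blockMirna,
                     blockSimple("snRNA", 150L, 150L, "snrna"))
    cursor <- gap() + 1L
    for (b in required) {
        w <- b(cursor)
        cursor <- cursor + w + gap()
    }
    if (cursor + 1000L > contigLength)
        stop("contigLength too small to host the required feature mix on ", ctg)
    oi <- 1L
    repeat {
        # worst-case block width ~1550 (coding); keep a trailing >= 1000 gap
        if (cursor + 1600L + 1000L > contigLength) break
        w <- optional[[oi]](cursor)
        cursor <- cursor + w + gap()
        oi <- if (oi == length(optional)) 1L else oi + 1L
    }
    df <- do.call(rbind, rows)
    GRanges(ctg, IRanges(df$start, df$end), strand = df$strand,
            feature_id = df$feature_id, biotype = df$biotype,
            parent_id = df$parent_id)
}

## Annotation-free gaps of at least `minWidth` nt on a contig.
.annotationGaps <- function(annotation, contig, minWidth = 1000L) {
    len <- seqlengths(annotation)[contig]
    ann <- annotation[as.character(seqnames(annotation)) == contig]
    cov <- reduce(IRanges(start(ann), end(ann)))
    gaps <- IRanges::gaps(cov, start = 1L, end = len)
    gaps[width(gaps) >= minWidth]
}

#' Plant ground-truth sRNA loci in a simulated annotation
#'
#' Builds the default planted-locus scenario: ~18 loci whose coordinates,
#' strands, genomic-context classes and per-contrast fold changes are known
#' in advance.  The set is designed to straddle every peak-calling
#' threshold: loci well above and below the 10x coverage rule, one locus
#' shorter than the 17 nt length floor and one longer than the 150 nt
#' ceiling, a zero-coverage locus, and representatives of every context
#' class (known = coincides with an annotated sRNA; nested sense/antisense;
#' overlapping a UTR; novel intergenic).  Two loci are universally
#' responsive across all four pathogen contrasts: one upregulated (+2
#' log2fc, the mir-243-3p analog) and one downregulated (-2, the mir-70
#' analog); a few others are bacterium- or generation-specific.
#'
#' @param annotation GRanges from [simulateGenomeAnnotation()].
#' @param design a [StudyDesign].
#' @param seed integer RNG seed (default: the design seed + 1).
#' @return GRanges with metadata columns `locus_id`, `truth_class`
#'   (`known`/`nested`/`overlapping`/`novel`), `truth_orientation`
#'   (`sense`/`antisense`/`n/a`), `target_mean_coverage` (pooled
#'   reads/base at neutral conditions), and `log2fc`, a numeric matrix with
#'   one column per pathogen contrast.
#' @examples
#' ga <- simulateGenomeAnnotation(1, 50000, seed = 7)
#' loci <- simulatePlantedLoci(ga$annotation, StudyDesign(seed = 7))
#' S4Vectors::mcols(loci)$truth_class
#' @export
simulatePlantedLoci <- function(annotation, design = StudyDesign(),
                                seed = design@seed + 1L) {
    contr <- designContrasts(design)$contrast_id
    bt <- mcols(annotation)$biotype
    ctg <- as.character(seqnames(annotation))
    firstCtg <- seqlevels(annotation)[1L]
    pick <- function(biotype, i = 1L) {
        sel <- which(bt == biotype & ctg == firstCtg)
        if (length(sel) < i)
            stop("annotation lacks a ", biotype, " feature to plant in")
        annotation[sel[i]]
    }
    .withSeed(seed, {
        rows <- list()
        addLocus <- function(gr, id, class, orient, cov, lfc = NULL) {
            m <- matrix(0, 1L, length(contr), dimnames = list(NULL, contr))
            if (!is.null(lfc)) m[1L, names(lfc)] <- lfc
            gr <- granges(gr)
            mcols(gr) <- DataFrame(locus_id = id, truth_class = class,
                                   truth_orientation = orient,
                                   target_mean_coverage = cov,
                                   log2fc = I(m))
            rows[[length(rows) + 1L]] <<- gr
        }
        # known loci: exact coordinates of annotated sRNAs
        mir1 <- pick("miRNA", 1L)
        addLocus(mir1, "mir243_analog", "known", "sense", 600,
                 setNames(rep(2, length(contr)), contr))
        pre2 <- pick("pre_miRNA", 2L)
        addLocus(pre2, "mir70_analog", "known", "sense", 600,
                 setNames(rep(-2, length(contr)), contr))
        mir3 <- pick("miRNA", 3L)
        addLocus(mir3, "known_neutral", "known", "sense", 50)
        # nested loci inside coding/rRNA features
        intron <- annotation[which(bt == "intron" & ctg == firstCtg)[1L]]
        s0 <- start(intron) + 20L
        addLocus(GRanges(firstCtg, IRanges(s0, s0 + 39L),
                         strand = strand(intron)),
                 "nested_intron_sense", "nested", "sense", 150,
                 c(PAO1_F1 = 2)[intersect("PAO1_F1", contr)])
        exon <- annotation[which(bt == "coding_exon" & ctg == firstCtg)[1L]]
        s0 <- start(exon) + 30L
        anti <- if (as.character(strand(exon)) == "+") "-" else "+"
        addLocus(GRanges(firstCtg, IRanges(s0, s0 + 29L), strand = anti),
                 "nested_exon_antisense", "nested", "antisense", 150,
                 setNames(c(2, 2), c("PAO1_F1", "PAO1_F2")))
        rrn <- pick("rRNA", 1L)
        s0 <- start(rrn) + 100L
        addLocus(GRanges(firstCtg, IRanges(s0, s0 + 24L), strand = strand(rrn)),
                 "nested_rrna_sense", "nested", "sense", 80,
                 c(PAO1_F2 = 2)[intersect("PAO1_F2", contr)])
        # overlapping: straddles a 3'UTR boundary
        utr <- annotation[which(bt == "three_prime_UTR" & ctg == firstCtg)[1L]]
        addLocus(GRanges(firstCtg, IRanges(end(utr) - 24L, end(utr) + 25L),
                         strand = strand(utr)),
                 "overlap_utr_sense", "overlapping", "sense", 150,
                 c(MST1_F2 = -2)[intersect("MST1_F2", contr)])
        # novel intergenic loci, one per gap, centered
        gapsAvail <- .annotationGaps(annotation, firstCtg)
        gapsAvail <- gapsAvail[order(-width(gapsAvail))]
        novel <- list(
            list("novel_plain",        60, 40, NULL),
            list("novel_down_paof1",   35, 80, c(PAO1_F1 = -2)),
            list("novel_up_mstf1",     30, 80, c(MST1_F1 = 2)),
            list("novel_low_cov",      40,  5, NULL),
            list("novel_zero_cov",     30,  0, NULL),
            list("novel_short16",      16, 50, NULL),
            list("novel_long160",     160, 50, NULL),
            list("novel_marginal",     25, 13, NULL),
            list("novel_neutral2",     90, 120, NULL),
            list("novel_neutral3",     22, 25, NULL),
            list("novel_up_both_gen", 100, 80,
                 setNames(c(2, 2), c("MST1_F1", "MST1_F2"))))
        if (length(gapsAvail) < length(novel))
            stop("not enough intergenic gaps to plant novel loci")
        for (j in seq_along(novel)) {
            spec <- novel[[j]]
            g <- gapsAvail[j]
            mid <- start(g) + (width(g) - spec[[2]]) %/% 2L
            lfc <- spec[[4]]
            if (!is.null(lfc)) lfc <- lfc[intersect(names(lfc), contr)]
            addLocus(GRanges(firstCtg, IRanges(mid, mid + spec[[2]] - 1L),
                             strand = sample(c("+", "-"), 1L)),
                     spec[[1]], "novel", "n/a", spec[[3]], lfc)
        }
        loci <- do.call(c, rows)
        seqlevels(loci) <- seqlevels(annotation)
        seqlengths(loci) <- seqlengths(annotation)
        loci
    })
}

## Per-library multiplier for a locus: 2^log2fc for the matching pathogen
## contrast, 1 for control libraries.
.lociMultipliers <- function(loci, design) {
    sheet <- sampleSheet(design)
    lfc <- mcols(loci)$log2fc
    mult <- matrix(1, nrow = length(loci), ncol = nrow(sheet),
                   dimnames = list(mcols(loci)$locus_id, sheet$sample_id))
    ctrl <- controlBacterium(design)
    for (j in seq_len(nrow(sheet))) {
        if (sheet$bacterium[j] == ctrl) next
        cid <- sprintf("%s_%s", sheet$bacterium[j], sheet$generation[j])
        if (cid %in% colnames(lfc)) mult[, j] <- 2^lfc[, cid]
    }
    mult
}

#' Simulate strand-aware alignments tiling planted loci
#'
#' For every library of the design, lays reads over each planted locus on a
#' fixed set of tiling offsets that cover the locus end to end (last offset
#' right-aligned), cycling through the offsets read by read, so per-base
#' coverage is near-uniform over the locus and zero outside it.  The pooled
#' read total per locus is fixed at its expectation, so the pooled mean
#' coverage hits `target_mean_coverage` times the mean condition multiplier
#' up to rounding; the reads are then allocated to libraries multinomially
#' in proportion to each library's condition multiplier (2^log2fc for the
#' matching pathogen contrast, 1 otherwise), which gives per-library counts
#' their sampling variability.  `target_mean_coverage` is calibrated as
#' pooled coverage across all libraries at multiplier 1.  A sprinkling of
#' background reads is placed on a coarse grid away from the loci, capped
#' at pooled depth 2.
#'
#' Loci narrower than `readLength` are tiled with reads of the locus width
#' (minimum 17 nt, the shortest legal read); a locus narrower than 17 nt is
#' covered by 17 nt reads anchored at its start, so its realized coverage
#' footprint is wider than the locus itself.
#'
#' @param loci GRanges from [simulatePlantedLoci()] (seqlengths required).
#' @param design a [StudyDesign].
#' @param readLength integer in 17..36; nominal read length (default 22 nt,
#'   a typical mature-miRNA length).
#' @param seed integer RNG seed (default: design seed + 2).
#' @param backgroundPerKb numeric; pooled background read starts per kb.
#' @return named list (one element per library, in sample-sheet order) of
#'   GRanges read records with a `qname` metadata column; seqlengths set.
#' @examples
#' ga <- simulateGenomeAnnotation(1, 50000, seed = 7)
#' loci <- simulatePlantedLoci(ga$annotation, StudyDesign(seed = 7))
#' aln <- simulateAlignments(loci, StudyDesign(seed = 7))
#' lengths(aln)[1:3]
#' @export
simulateAlignments <- function(loci, design = StudyDesign(), readLength = 22L,
                               seed = design@seed + 2L, backgroundPerKb = 1) {
    stopifnot(readLength >= 17L, readLength <= 36L)
    sl <- seqlengths(loci)
    if (any(is.na(sl))) stop("loci must carry seqlengths")
    if (any(start(loci) < 1L) ||
        any(end(loci) > sl[as.character(seqnames(loci))]))
        stop("planted locus outside contig bounds")
    sheet <- sampleSheet(design)
    mult <- .lociMultipliers(loci, design)
    nS <- nrow(sheet)
    .withSeed(seed, {
        perSample <- rep(list(list()), nS)
        for (i in seq_along(loci)) {
            W <- width(loci)[i]
            tgt <- mcols(loci)$target_mean_coverage[i]
            if (tgt <= 0) next
            readW <- if (W >= readLength) readLength else max(W, 17L)
            nPer <- max(1L, as.integer(ceiling(W / readW)))
            starts <- start(loci)[i] + (seq_len(nPer) - 1L) * readW
            starts[nPer] <- max(start(loci)[i], end(loci)[i] - readW + 1L)
            lam <- tgt * mult[i, ] * W / (readW * nS)
            total <- as.integer(round(sum(lam)))
            if (total == 0L) next
            alloc <- tabulate(sample.int(nS, total, replace = TRUE,
                                         prob = lam), nbins = nS)
            for (j in seq_len(nS)) {
                k <- alloc[j]
                if (k == 0L) next
                off <- sample.int(nPer, 1L)   # random phase of the tiling cycle
                st <- starts[((off + seq_len(k) - 2L) %% nPer) + 1L]
                perSample[[j]][[length(perSample[[j]]) + 1L]] <-
                    GRanges(seqnames(loci)[i], IRanges(st, width = readW),
                            strand = strand(loci)[i])
            }
        }
        # background: grid positions >= 200 nt from any locus, pooled depth <= 2
        for (ctg in names(sl)) {
            grid <- seq(1L, sl[ctg] - readLength, by = 150L)
            lc <- loci[as.character(seqnames(loci)) == ctg]
            if (length(lc)) {
                bad <- IRanges(start(lc) - 200L - readLength, end(lc) + 200L)
                keep <- !IRanges::overlapsAny(IRanges(grid, width = readLength), bad)
                grid <- grid[keep]
            }
            nbg <- min(length(grid), round(backgroundPerKb * sl[ctg] / 1000))
            if (nbg == 0L) next
            pos <- sample(grid, nbg)
            for (p in pos) {
                ncopies <- sample(1:2, 1L)
                j <- sample(nS, ncopies, replace = FALSE)
                for (jj in j)
                    perSample[[jj]][[length(perSample[[jj]]) + 1L]] <-
                        GRanges(ctg, IRanges(p, width = readLength),
                                strand = sample(c("+", "-"), 1L))
            }
        }
        out <- vector("list", nS)
        names(out) <- sheet$sample_id
        for (j in seq_len(nS)) {
            gr <- if (length(perSample[[j]])) {
                suppressWarnings(do.call(c, perSample[[j]]))
            } else GRanges()
            seqlevels(gr) <- names(sl)
            seqlengths(gr) <- sl
            gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
            if (length(gr))
                mcols(gr)$qname <- sprintf("%s_read%06d", sheet$sample_id[j],
                                           seq_along(gr))
            else mcols(gr)$qname <- character(0)
            out[[j]] <- gr
        }
        out
    })
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Draws counts for every feature x library cell from a negative binomial
#' with mean `baselineMean * 2^log2fc(condition) * sizeFactor` and
#' dispersion `dispersion` (variance mu + dispersion * mu^2); dispersion 0
#' degrades to Poisson.  Deterministic for a fixed seed.
#'
#' @param featureIds character; feature identifiers (rownames of the result).
#' @param design a [StudyDesign].
#' @param baselineMean positive numeric; expected count at neutral
#'   conditions and size factor 1.  Scalar or per-feature vector.
#' @param dispersion numeric >= 0; NB dispersion phi.
#' @param log2fc optional numeric matrix, features x contrast ids; planted
#'   log2 fold changes (pathogen over control).  Default: all zero.
#' @param sizeFactors optional positive numeric per library; default all 1.
#' @param seed integer RNG seed.
#' @return integer matrix, features x libraries (sample-sheet order).
#' @examples
#' cm <- simulateCounts(paste0("f", 1:5), StudyDesign(), 100, 0.1, seed = 3)
#' dim(cm)
#' @export
simulateCounts <- function(featureIds, design = StudyDesign(),
                           baselineMean = 100, dispersion = 0.1,
                           log2fc = NULL, sizeFactors = NULL,
                           seed = design@seed + 3L) {
    if (any(baselineMean <= 0)) stop("baselineMean must be positive")
    if (dispersion < 0) stop("dispersion must be >= 0")
    sheet <- sampleSheet(design)
    nF <- length(featureIds); nS <- nrow(sheet)
    if (is.null(sizeFactors)) sizeFactors <- rep(1, nS)
    stopifnot(length(sizeFactors) == nS, all(sizeFactors > 0))
    ctrl <- controlBacterium(design)
    mu <- matrix(rep(baselineMean, length.out = nF), nF, nS)
    if (!is.null(log2fc)) {
        stopifnot(nrow(log2fc) == nF)
        for (j in seq_len(nS)) {
            if (sheet$bacterium[j] == ctrl) next
            cid <- sprintf("%s_%s", sheet$bacterium[j], sheet$generation[j])
            if (cid %in% colnames(log2fc)) mu[, j] <- mu[, j] * 2^log2fc[, cid]
        }
    }
    mu <- sweep(mu, 2L, sizeFactors, `*`)
    .withSeed(seed, {
        counts <- if (dispersion == 0) {
            rpois(nF * nS, lambda = as.vector(mu))
        } else {
            rnbinom(nF * nS, mu = as.vector(mu), size = 1 / dispersion)
        }
        matrix(as.integer(counts), nF, nS,
               dimnames = list(featureIds, sheet$sample_id))
    })
}
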