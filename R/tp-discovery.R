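## Transcriptional-peak (TP) discovery: strand-specific per-base coverage
## from pooled libraries, segmented into maximal runs of depth strictly
## greater than the peak threshold, then filtered by length (17..150 nt,
## inclusive) and mean coverage (>= 10, inclusive).  The two thresholds use
## deliberately different operators: a base belongs to a peak only if its
## depth exceeds 10 ("more than 10 per base"), while the retained feature's
## average needs only to reach 10 ("10 or more reads by nucleotide").

#' Pool alignments and build strand-specific coverage
#'
#' Sums per-base read depth over all supplied libraries, separately per
#' strand, over the full length of each contig.  Peaks are intended to be
#' called on this pooled track (the libraries are merged before peak
#' definition), not per sample.
#'
#' @param samples a GRanges of reads, or a list of them (one per library).
#' @param contigLengths named integer vector of contig lengths; defaults to
#'   the seqlengths carried by the records.
#' @return a [StrandedCoverage-class] object.
#' @examples
#' reads <- GenomicRanges::GRanges("c1", IRanges::IRanges(rep(101, 12), width = 36),
#'                                 strand = "-", seqlengths = c(c1 = 1000))
#' cov <- poolCoverage(reads)
#' max(coverageTrack(cov, "-")$c1)
#' @export
poolCoverage <- function(samples, contigLengths = NULL) {
    if (is(samples, "GRanges")) samples <- list(samples)
    pooled <- suppressWarnings(do.call(c, unname(lapply(samples, granges))))
    if (is.null(contigLengths)) {
        contigLengths <- seqlengths(pooled)
        if (length(contigLengths) == 0L || any(is.na(contigLengths)))
            stop("supply contigLengths or records with seqlengths")
    }
    seqlevels(pooled) <- names(contigLengths)
    if (length(pooled) &&
        (any(start(pooled) < 1L) ||
         any(end(pooled) > contigLengths[as.character(seqnames(pooled))])))
        stop("alignment record beyond contig bounds")
    str <- as.character(strand(pooled))
    if (any(str == "*"))
        stop("alignment records must be stranded (+/-)")
    mkTrack <- function(s) {
        coverage(pooled[str == s],
                 width = as.list(setNames(as.integer(contigLengths),
                                          names(contigLengths))))
    }
    new("StrandedCoverage", plus = mkTrack("+"), minus = mkTrack("-"))
}

#' Segment a coverage track into candidate peak intervals
#'
#' Returns the maximal runs of consecutive bases whose depth is strictly
#' greater than `peakThreshold`; a single sub-threshold base splits a run.
#' Optionally, runs separated by at most `mergeGap` sub-threshold bases are
#' merged (default 0: no merging).
#'
#' @param depth an [S4Vectors::Rle] (or plain vector) of per-base depths for
#'   one contig and strand.
#' @param peakThreshold numeric; a base is in a peak iff depth > this.
#'   Default 10.
#' @param mergeGap integer >= 0; maximal gap bridged between runs.
#' @return an [IRanges::IRanges] of candidate intervals (1-based, closed).
#' @examples
#' segmentPeaks(S4Vectors::Rle(c(0, 11, 11, 10, 12, 0)))
#' @export
segmentPeaks <- function(depth, peakThreshold = 10, mergeGap = 0L) {
    stopifnot(peakThreshold >= 0, mergeGap >= 0L)
    if (!is(depth, "Rle")) depth <- S4Vectors::Rle(depth)
    ir <- slice(depth, lower = peakThreshold, includeLower = FALSE,
                rangesOnly = TRUE)
    if (mergeGap > 0L) ir <- reduce(ir, min.gapwidth = mergeGap + 1L)
    ir
}

#' Filter candidate intervals into transcriptional peaks
#'
#' Keeps candidates whose length lies within `[minLen, maxLen]` (inclusive
#' on both ends) and whose mean depth over their own bases is at least
#' `minMeanCov` (inclusive), and annotates them with mean and max coverage.
#'
#' @param candidates IRanges from [segmentPeaks()].
#' @param depth the same per-base depth the candidates were segmented from.
#' @param minLen,maxLen integer length bounds in nt (defaults 17 and 150).
#' @param minMeanCov numeric; minimal mean depth (default 10).
#' @return a data.frame with columns `start`, `end`, `length`,
#'   `mean_coverage`, `max_coverage` (1-based, closed coordinates).
#' @export
filterPeaks <- function(candidates, depth, minLen = 17L, maxLen = 150L,
                        minMeanCov = 10) {
    if (!is(depth, "Rle")) depth <- S4Vectors::Rle(depth)
    if (length(candidates) == 0L)
        return(data.frame(start = integer(0), end = integer(0),
                          length = integer(0), mean_coverage = numeric(0),
                          max_coverage = numeric(0)))
    v <- Views(depth, candidates)
    mn <- viewMeans(v)
    mx <- viewMaxs(v)
    keep <- width(candidates) >= minLen & width(candidates) <= maxLen &
        mn >= minMeanCov
    data.frame(start = start(candidates)[keep], end = end(candidates)[keep],
               length = width(candidates)[keep], mean_coverage = mn[keep],
               max_coverage = mx[keep])
}

#' Call transcriptional peaks from pooled alignments
#'
#' End-to-end TP caller: pools the libraries into strand-specific coverage,
#' segments each contig and strand independently (depth strictly greater
#' than `peakThreshold`), filters by length and mean coverage, and returns
#' the peaks of both strands gathered and sorted by contig then start.
#' Peak ids are stable: `TP_<contig>_<strand>_<start>`.
#'
#' @param samples GRanges of reads or a list of them (one per library), or a
#'   [StrandedCoverage-class] object built beforehand.
#' @param contigLengths named integer vector (see [poolCoverage()]).
#' @param peakThreshold numeric; per-base depth must exceed this (default 10).
#' @param minLen,maxLen integer; retained length bounds, inclusive
#'   (defaults 17 and 150 nt).
#' @param minMeanCov numeric; minimal mean depth, inclusive (default 10).
#' @param mergeGap integer; see [segmentPeaks()] (default 0).
#' @return GRanges with metadata columns `tp_id`, `length`, `mean_coverage`,
#'   `max_coverage`.
#' @examples
#' reads <- GenomicRanges::GRanges("c1", IRanges::IRanges(rep(101, 12), width = 30),
#'                                 strand = "+", seqlengths = c(c1 = 1000))
#' callPeaks(reads)
#' @export
callPeaks <- function(samples, contigLengths = NULL, peakThreshold = 10,
                      minLen = 17L, maxLen = 150L, minMeanCov = 10,
                      mergeGap = 0L) {
    cov <- if (is(samples, "StrandedCoverage")) samples
           else poolCoverage(samples, contigLengths)
    out <- list()
    for (s in c("+", "-")) {
        trk <- coverageTrack(cov, s)
        for (ctg in names(trk)) {
            cand <- segmentPeaks(trk[[ctg]], peakThreshold, mergeGap)
            df <- filterPeaks(cand, trk[[ctg]], minLen, maxLen, minMeanCov)
            if (nrow(df) == 0L) next
            out[[length(out) + 1L]] <-
                GRanges(ctg, IRanges(df$start, df$end), strand = s,
                        tp_id = sprintf("TP_%s_%s_%d", ctg,
                                        ifelse(s == "+", "plus", "minus"),
                                        df$start),
                        length = df$length, mean_coverage = df$mean_coverage,
                        max_coverage = df$max_coverage)
        }
    }
    if (length(out) == 0L) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(tp_id = character(0), length = integer(0),
                               mean_coverage = numeric(0),
                               max_coverage = numeric(0))
        return(gr)
    }
    gr <- suppressWarnings(do.call(c, out))
    lens <- vapply(coverageTrack(cov, "+"), length, integer(1))
    seqlevels(gr) <- names(lens)
    seqlengths(gr) <- lens
    gr[order(as.character(seqnames(gr)), start(gr))]
}
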