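## Read counting over peak features, featureCounts-style defaults: a read is
## assigned to a feature when their spans intersect by at least minOverlap
## bases (default 1); a read intersecting more than one feature is discarded
## as ambiguous; default mode is unstranded.

#' Count reads over features for one library
#'
#' @param features GRanges of counting features (metadata column `tp_id` or
#'   `feature_id` used as names; falls back to positional names).
#' @param reads GRanges of mapped reads for one library.
#' @param mode `"any_overlap_unstranded"` (default) or
#'   `"any_overlap_stranded"`; in stranded mode read and feature strands
#'   must agree.
#' @param minOverlap integer >= 1; minimal intersecting bases.
#' @return list with `counts` (named integer vector over features),
#'   `assigned`, `ambiguous`, `unassigned_no_feature`, `unassigned_contig`
#'   (reads on contigs absent from the feature universe) and `total`.  The
#'   four read buckets always sum to `total`.
#' @examples
#' f <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(100, 300), width = 50),
#'                             tp_id = c("a", "b"))
#' r <- GenomicRanges::GRanges("c1", IRanges::IRanges(110, 130), strand = "+",
#'                             qname = "r1")
#' countReads(f, r)$counts
#' @export
countReads <- function(features, reads,
                       mode = c("any_overlap_unstranded",
                                "any_overlap_stranded"),
                       minOverlap = 1L) {
    mode <- match.arg(mode)
    stopifnot(minOverlap >= 1L)
    ids <- mcols(features)$tp_id
    if (is.null(ids)) ids <- mcols(features)$feature_id
    if (is.null(ids)) ids <- sprintf("feature%06d", seq_along(features))
    total <- length(reads)
    knownCtg <- as.character(seqnames(reads)) %in%
        as.character(unique(seqnames(features)))
    nUnknown <- sum(!knownCtg)
    if (nUnknown > 0)
        message(nUnknown, " read(s) on contigs without features ",
                "(unassigned_contig)")
    reads2 <- reads[knownCtg]
    hits <- suppressWarnings(  # read/feature seqlevel sets may differ
        findOverlaps(reads2, features, minoverlap = minOverlap,
                     ignore.strand = (mode == "any_overlap_unstranded")))
    nh <- tabulate(queryHits(hits), nbins = length(reads2))
    uniqueHit <- nh == 1L
    counts <- tabulate(subjectHits(hits)[uniqueHit[queryHits(hits)]],
                       nbins = length(features))
    list(counts = setNames(as.integer(counts), ids),
         assigned = sum(uniqueHit),
         ambiguous = sum(nh > 1L),
         unassigned_no_feature = sum(nh == 0L),
         unassigned_contig = nUnknown,
         total = total)
}

#' Assemble per-library counts into a SummarizedExperiment
#'
#' @param perSampleCounts named list of [countReads()] results (or plain
#'   named count vectors), one per library; all over the same feature
#'   universe.
#' @param sheet sample sheet data.frame ([sampleSheet()]); column order of
#'   the result follows it.
#' @param features optional GRanges of the counting features (becomes
#'   `rowRanges`).
#' @return a [SummarizedExperiment::SummarizedExperiment] (ranged if
#'   `features` given) with assay `counts`, `colData` from the sheet, and
#'   per-library totals in `metadata()$library_size`.
#' @export
assembleCountMatrix <- function(perSampleCounts, sheet, features = NULL) {
    if (anyDuplicated(sheet$sample_id))
        stop("duplicated sample_id in sample sheet: ",
             paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
                   collapse = ", "))
    missing <- setdiff(sheet$sample_id, names(perSampleCounts))
    if (length(missing))
        stop("no counts supplied for sample(s): ",
             paste(missing, collapse = ", "))
    getVec <- function(x) if (is.list(x)) x$counts else x
    vecs <- lapply(perSampleCounts[sheet$sample_id], getVec)
    fids <- names(vecs[[1L]])
    for (v in vecs)
        if (!identical(names(v), fids))
            stop("samples do not share an identical feature universe")
    m <- do.call(cbind, vecs)
    dimnames(m) <- list(fids, sheet$sample_id)
    libsz <- vapply(perSampleCounts[sheet$sample_id],
                    function(x) if (is.list(x)) x$total else sum(x),
                    numeric(1))
    cd <- DataFrame(sheet, row.names = sheet$sample_id)
    se <- if (!is.null(features)) {
        stopifnot(length(features) == nrow(m))
        SummarizedExperiment(assays = list(counts = m), rowRanges = features,
                             colData = cd)
    } else {
        SummarizedExperiment(assays = list(counts = m), colData = cd)
    }
    metadata(se)$library_size <- libsz
    se
}
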