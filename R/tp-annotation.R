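## Genomic-context classification of transcriptional peaks.  Decision
## cascade per peak: (1) known if it matches an annotated sRNA-biotype
## feature on the same strand with reciprocal overlap above a threshold;
## (2) else partially novel / nested if fully contained in any feature
## (either strand); (3) else partially novel / overlapping if it partially
## intersects any feature; (4) else novel / intergenic.  Classification is
## against leaf features (exon, intron, UTRs, the sRNAs themselves), so a
## peak inside an intron is "nested in an intron", not "inside a gene".

#' Default sRNA biotypes for the "known" rule
#'
#' A peak counts as a known sRNA only when it matches a feature of one of
#' these biotypes.  rRNA and lincRNA are deliberately excluded: peaks inside
#' them are partially novel (nested), which is how rRNA-internal fragments
#' are reported.
#'
#' @return character vector of biotypes.
#' @export
srnaBiotypes <- function() .SRNA_BIOTYPES

#' Classify transcriptional peaks by genomic context
#'
#' @param tps GRanges of peaks (metadata column `tp_id`).
#' @param annotation GRanges of annotation features (metadata columns
#'   `feature_id`, `biotype`), as from [readAnnotation()] or
#'   [simulateGenomeAnnotation()].
#' @param srnaBiotypes character; biotypes eligible for the "known" call.
#' @param minReciprocalOverlap numeric in (0, 1]; a peak matches an
#'   annotated sRNA when the overlap covers at least this fraction of both
#'   the peak and the feature.  Default 0.8.
#' @param requireSameStrand logical; known calls require strand agreement
#'   (default TRUE).
#' @return data.frame with one row per peak: `tp_id`, `category`
#'   (`known`/`partially_novel`/`novel`), `relation` (`exact_srna_match`/
#'   `nested`/`overlapping`/`intergenic`), `orientation`
#'   (`sense`/`antisense`/`n/a`), `host_feature_ids` and `host_biotypes`
#'   (comma-collapsed lists of every intersecting feature).  Orientation is
#'   taken from the host with the largest overlap, ties broken by the
#'   smallest feature, then by feature id.
#' @examples
#' ga <- simulateGenomeAnnotation(1, 50000, seed = 7)
#' mir <- ga$annotation[S4Vectors::mcols(ga$annotation)$biotype == "miRNA"][1]
#' tp <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(mir),
#'                              IRanges::ranges(mir), strand = BiocGenerics::strand(mir),
#'                              tp_id = "TP_demo")
#' classifyTps(tp, ga$annotation)$category
#' @export
classifyTps <- function(tps, annotation, srnaBiotypes = .SRNA_BIOTYPES,
                        minReciprocalOverlap = 0.8,
                        requireSameStrand = TRUE) {
    stopifnot(minReciprocalOverlap > 0, minReciprocalOverlap <= 1)
    n <- length(tps)
    ids <- mcols(tps)$tp_id
    if (is.null(ids)) ids <- sprintf("TP_%06d", seq_len(n))
    category <- character(n); relation <- character(n)
    orientation <- character(n)
    hostIds <- character(n); hostBts <- character(n)
    hits <- findOverlaps(tps, annotation, ignore.strand = TRUE)
    q <- queryHits(hits); s <- subjectHits(hits)
    ovW <- width(pintersect(granges(tps)[q], granges(annotation)[s],
                            ignore.strand = TRUE))
    annBt <- mcols(annotation)$biotype
    annId <- mcols(annotation)$feature_id
    annStr <- as.character(strand(annotation))
    tpStr <- as.character(strand(tps))
    for (i in seq_len(n)) {
        sel <- which(q == i)
        if (length(sel) == 0L) {
            category[i] <- "novel"; relation[i] <- "intergenic"
            orientation[i] <- "n/a"; hostIds[i] <- ""; hostBts[i] <- ""
            next
        }
        f <- s[sel]; ov <- ovW[sel]
        hostIds[i] <- paste(annId[f], collapse = ",")
        hostBts[i] <- paste(annBt[f], collapse = ",")
        # (1) known: sRNA biotype, reciprocal overlap, strand agreement
        recip <- ov / width(tps)[i] >= minReciprocalOverlap &
            ov / width(annotation)[f] >= minReciprocalOverlap
        isSrna <- annBt[f] %in% srnaBiotypes
        sameStr <- annStr[f] == tpStr[i]
        knownHit <- recip & isSrna & (sameStr | !requireSameStrand)
        if (any(knownHit)) {
            category[i] <- "known"; relation[i] <- "exact_srna_match"
            kk <- which(knownHit)
            best <- kk[order(-ov[kk], width(annotation)[f[kk]], annId[f[kk]])][1L]
            orientation[i] <- if (annStr[f[best]] == tpStr[i]) "sense" else "antisense"
            next
        }
        contained <- start(annotation)[f] <= start(tps)[i] &
            end(annotation)[f] >= end(tps)[i]
        category[i] <- "partially_novel"
        relation[i] <- if (any(contained)) "nested" else "overlapping"
        best <- sel[order(-ov, width(annotation)[f], annId[f])][1L]
        orientation[i] <- if (annStr[s[best]] == tpStr[i]) "sense" else "antisense"
    }
    data.frame(tp_id = ids, category = category, relation = relation,
               orientation = orientation, host_feature_ids = hostIds,
               host_biotypes = hostBts, stringsAsFactors = FALSE)
}

#' Summarize peak classifications
#'
#' @param classifications data.frame from [classifyTps()].
#' @return list with elements `n`, `counts` and `fractions` (named by
#'   category: known, partially_novel, novel; fractions sum to 1),
#'   `by_relation`, `by_orientation`, and `by_host_biotype` (table over the
#'   individual host biotypes of non-novel peaks).
#' @export
summarizeClasses <- function(classifications) {
    if (is.null(classifications) || nrow(classifications) == 0L)
        stop("cannot summarize an empty classification set")
    cats <- c("known", "partially_novel", "novel")
    counts <- setNames(integer(3), cats)
    tab <- table(classifications$category)
    counts[names(tab)] <- as.integer(tab)
    hostBts <- unlist(strsplit(classifications$host_biotypes[
        classifications$host_biotypes != ""], ","))
    list(n = nrow(classifications),
         counts = counts,
         fractions = counts / sum(counts),
         by_relation = table(classifications$relation),
         by_orientation = table(classifications$orientation),
         by_host_biotype = if (length(hostBts)) table(hostBts) else table(character(0)))
}
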