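## Set logic across the four pathogen x generation contrasts.  Feature
## identity is the TP id from the single pooled peak call, so membership is
## well-defined across contrasts.

#' Build the cross-contrast Venn report for one direction
#'
#' @param deTables named list of per-contrast DE data.frames
#'   ([runConsensusDE()]); all contrasts of the design must be present.
#' @param direction `"up"` or `"down"`.
#' @param design a [StudyDesign] naming the expected contrasts.
#' @return a [SharedFeatureReport-class]: per-feature contrast membership
#'   plus the shared-in-all, bacterium-specific (both generations of
#'   exactly one pathogen) and generation-specific (a single contrast)
#'   cells.
#' @examples
#' tab <- function(id, call) data.frame(feature_id = id, call = call)
#' de <- list(PAO1_F1 = tab("t1", "up"), PAO1_F2 = tab("t1", "up"),
#'            MST1_F1 = tab("t1", "up"), MST1_F2 = tab("t1", "up"))
#' sharedAll(buildVenn(de, "up"))
#' @export
buildVenn <- function(deTables, direction = c("up", "down"),
                      design = StudyDesign()) {
    direction <- match.arg(direction)
    contr <- designContrasts(design)
    absent <- setdiff(contr$contrast_id, names(deTables))
    if (length(absent))
        stop("missing contrast(s): ", paste(absent, collapse = ", "))
    deTables <- deTables[contr$contrast_id]
    membership <- list()
    for (cid in contr$contrast_id) {
        tab <- deTables[[cid]]
        hits <- tab$feature_id[tab$call == direction]
        for (f in hits) membership[[f]] <- c(membership[[f]], cid)
    }
    membership <- lapply(membership, sort)
    feats <- names(membership)
    if (is.null(feats)) feats <- character(0)
    nContr <- nrow(contr)
    shared <- feats[vapply(membership, length, 0L) == nContr]
    generationSpec <- feats[vapply(membership, length, 0L) == 1L]
    bacteriumSpec <- feats[vapply(membership, function(m) {
        bs <- unique(contr$bacterium[match(m, contr$contrast_id)])
        length(bs) == 1L &&
            setequal(m, contr$contrast_id[contr$bacterium == bs])
    }, logical(1)) & vapply(membership, length, 0L) > 1L]
    new("SharedFeatureReport", direction = direction,
        contrasts = contr$contrast_id, membership = membership,
        sharedAll = as.character(sort(shared)),
        bacteriumSpecific = as.character(sort(bacteriumSpec)),
        generationSpecific = as.character(sort(generationSpec)))
}

#' Venn-cell counts
#'
#' @param report a [SharedFeatureReport-class].
#' @return named integer vector: number of DE features per non-empty
#'   contrast subset (names are `+`-joined contrast ids).  The counts sum
#'   to the number of DE features in the union.
#' @export
vennCells <- function(report) {
    cells <- vapply(report@membership, paste, "", collapse = "+")
    table(cells)
}

#' Flag universally responsive features
#'
#' Emits the shared-in-all-contrasts members of each direction -- the
#' operation that singles out a transcript upregulated in both generations
#' on both pathogens (and the symmetric universally downregulated set) --
#' annotated with their per-contrast log2 fold changes and, when a
#' classification table is supplied, their genomic-context category.
#'
#' @param reportUp,reportDown [SharedFeatureReport-class] objects for the
#'   two directions.
#' @param deTables the per-contrast DE tables the reports were built from.
#' @param classifications optional data.frame from [classifyTps()].
#' @return data.frame: `feature_id`, `direction`, one `log2fc_<contrast>`
#'   column per contrast, and (if available) `category`, `relation`,
#'   `orientation`.  Zero rows when no universal feature exists.
#' @export
flagUniversalCandidates <- function(reportUp, reportDown, deTables,
                                    classifications = NULL) {
    one <- function(report) {
        feats <- sharedAll(report)
        if (length(feats) == 0L)
            return(NULL)
        df <- data.frame(feature_id = feats, direction = report@direction,
                         stringsAsFactors = FALSE)
        for (cid in report@contrasts) {
            tab <- deTables[[cid]]
            df[[paste0("log2fc_", cid)]] <-
                tab$log2fc[match(feats, tab$feature_id)]
        }
        df
    }
    out <- rbind(one(reportUp), one(reportDown))
    if (is.null(out))
        out <- data.frame(feature_id = character(0), direction = character(0),
                          stringsAsFactors = FALSE)
    if (!is.null(classifications) && nrow(out)) {
        idx <- match(out$feature_id, classifications$tp_id)
        out$category <- classifications$category[idx]
        out$relation <- classifications$relation[idx]
        out$orientation <- classifications$orientation[idx]
    }
    out
}
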