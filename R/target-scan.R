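## miRNA target screen: maximal contiguous perfect-complement seed search
## between a mature miRNA and candidate transcripts, plus nearest-neighbor
## hybridization free energy of the seed helix.  The decision variables are
## the seed length (reported hits need seed >= minSeed, capped at maxSeed)
## and the free energy at the experiment temperature.

.RNA_CODE <- c(A = 1L, C = 2L, G = 3L, U = 4L)

.normalizeRna <- function(x, what = "sequence") {
    x <- toupper(as.character(x))
    if (grepl("T", x)) {
        warning("T converted to U in ", what)
        x <- gsub("T", "U", x)
    }
    chars <- strsplit(x, "")[[1L]]
    if (!all(chars %in% names(.RNA_CODE)))
        stop("invalid RNA alphabet in ", what, ": ",
             paste(unique(setdiff(chars, names(.RNA_CODE))), collapse = ","))
    chars
}

.pairMatrix <- function(allowGU) {
    p <- matrix(FALSE, 4L, 4L, dimnames = list(names(.RNA_CODE),
                                               names(.RNA_CODE)))
    p["A", "U"] <- p["U", "A"] <- p["G", "C"] <- p["C", "G"] <- TRUE
    if (allowGU) p["G", "U"] <- p["U", "G"] <- TRUE
    p
}

#' Longest contiguous perfect-complement seed
#'
#' Finds the maximal-length contiguous antiparallel perfect
#' Watson-Crick-complement match (A-U, G-C; G-U only if
#' `allowGU`) between a miRNA and a target sequence.  The reported length
#' is capped at `maxSeed` of the config; ties are broken by the smallest
#' target start, then the smallest miRNA start.
#'
#' @param mirna,target RNA sequences (character or
#'   [Biostrings::RNAString]); T is auto-converted to U with a warning.
#' @param config a [ScanConfig-class].
#' @return list with `seed_length` (0 if no base can pair), `mirna_span`
#'   and `target_span` ([IRanges::IRanges], 1-based closed, empty when
#'   seed_length is 0), and `has_gu` (does the seed use a wobble pair).
#' @examples
#' longestComplementSeed("ACGGAUCC", "AAGGAUCCGUAA")$seed_length
#' @export
longestComplementSeed <- function(mirna, target, config = ScanConfig()) {
    m <- .normalizeRna(mirna, "miRNA")
    t <- .normalizeRna(target, "target")
    if (length(m) < 8L || length(t) < 8L)
        stop("sequences must be at least 8 nt")
    pm <- .pairMatrix(config@allowGU)
    M <- pm[m, t, drop = FALSE]  # M[i, j]: can mirna[i] pair target[j]
    n <- length(m); nt <- length(t)
    best <- list(len = 0L, i = NA_integer_, j = NA_integer_)
    runs <- list()
    maxRun <- 0L
    for (d in 2L:(n + nt)) {   # pairing (i, j): stacking runs keep i + j fixed
        i <- max(1L, d - nt):min(n, d - 1L)
        v <- M[cbind(i, d - i)]
        r <- rle(v)
        if (!any(r$values)) next
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (k in which(r$values)) {
            runs[[length(runs) + 1L]] <-
                c(len = r$lengths[k], i0 = i[1L] + starts[k] - 1L, d = d)
            maxRun <- max(maxRun, r$lengths[k])
        }
    }
    if (maxRun == 0L)
        return(list(seed_length = 0L, mirna_span = IRanges(),
                    target_span = IRanges(), has_gu = FALSE))
    L <- min(maxRun, config@maxSeed)
    cand <- NULL
    for (r in runs) {
        if (r[["len"]] < L) next
        o <- 0:(r[["len"]] - L)
        i1 <- r[["i0"]] + o
        jStart <- r[["d"]] - (i1 + L - 1L)
        cand <- rbind(cand, cbind(i1 = i1, jStart = jStart))
    }
    pickIdx <- order(cand[, "jStart"], cand[, "i1"])[1L]
    i1 <- cand[pickIdx, "i1"]; j1 <- cand[pickIdx, "jStart"]
    mirnaSpan <- IRanges(i1, i1 + L - 1L)
    targetSpan <- IRanges(j1, j1 + L - 1L)
    seedM <- m[i1:(i1 + L - 1L)]
    seedT <- t[(j1 + L - 1L):j1]
    hasGU <- any((seedM == "G" & seedT == "U") | (seedM == "U" & seedT == "G"))
    list(seed_length = as.integer(L), mirna_span = mirnaSpan,
         target_span = targetSpan, has_gu = hasGU)
}

## Stack free energy lookup with strand-flip symmetry:
## (top, bottom) == (rev(bottom), rev(top)).
.stackEnergy <- function(top, bottom, tempK, tab) {
    hit <- which(tab$top == top & tab$bottom == bottom)
    if (length(hit) == 0L) {
        rev2 <- function(x) paste(rev(strsplit(x, "")[[1L]]), collapse = "")
        hit <- which(tab$top == rev2(bottom) & tab$bottom == rev2(top))
    }
    if (length(hit) == 0L)
        stop("no nearest-neighbor parameters for stack ", top, "/", bottom)
    tab$dH[hit[1L]] - tempK * tab$dS[hit[1L]] / 1000
}

#' Nearest-neighbor hybridization free energy of a duplex window
#'
#' Computes `deltaG(T)` of a fully paired antiparallel RNA/RNA helix as the
#' duplex-initiation term plus the sum of stacked-pair terms
#' (`dH - T*dS`), plus a terminal-A-U penalty per helix end closed by an
#' A-U pair, using the shipped Watson-Crick parameter table
#' ([nnParameters()]).  Both windows are given 5'->3'; position k of the
#' miRNA window pairs position `length - k + 1` of the target window.
#' Every opposed position must form a Watson-Crick pair (the parameter set
#' does not cover G-U stacks), and at least two pairs are required.
#'
#' @param mirnaWindow,targetWindow equal-length RNA sequences (>= 2 nt).
#' @param temperature temperature in degrees Celsius (default 20).
#' @param nnParameterSet identifier passed to [nnParameters()].
#' @return free energy in kcal/mol (negative = favorable).
#' @examples
#' duplexEnergy("GC", "GC")   # one GC/CG stack + initiation
#' @export
duplexEnergy <- function(mirnaWindow, targetWindow, temperature = 20,
                         nnParameterSet = "xia1998") {
    m <- .normalizeRna(mirnaWindow, "miRNA window")
    t <- .normalizeRna(targetWindow, "target window")
    L <- length(m)
    if (length(t) != L) stop("windows must have equal length")
    if (L < 2L) stop("need at least two consecutive base pairs")
    bottom <- rev(t)  # bottom[k] is paired under m[k]
    pm <- .pairMatrix(allowGU = FALSE)
    if (!all(pm[cbind(m, bottom)]))
        stop("windows do not form a fully Watson-Crick-paired duplex")
    tab <- nnParameters(nnParameterSet)
    tempK <- temperature + 273.15
    init <- attr(tab, "initiation")
    termAU <- attr(tab, "terminal_AU")
    dG <- init[["dH"]] - tempK * init[["dS"]] / 1000
    for (k in seq_len(L - 1L)) {
        dG <- dG + .stackEnergy(paste0(m[k], m[k + 1L]),
                                paste0(bottom[k], bottom[k + 1L]),
                                tempK, tab)
    }
    auEnd <- function(a, b) (a == "A" && b == "U") || (a == "U" && b == "A")
    nAU <- auEnd(m[1L], bottom[1L]) + auEnd(m[L], bottom[L])
    dG + nAU * (termAU[["dH"]] - tempK * termAU[["dS"]] / 1000)
}

#' Screen candidate transcripts for miRNA seed targets
#'
#' Runs [longestComplementSeed()] against every candidate, keeps hits with
#' seed length at least `minSeed`, attaches the seed helix free energy at
#' the configured temperature, and ranks by seed length (descending), then
#' free energy (ascending), then target id.  Seeds containing G-U wobble
#' pairs (possible only with `allowGU = TRUE`) get `NA` energy, as the
#' shipped parameter table is Watson-Crick-only.
#'
#' @param mirna named single RNA sequence (character or
#'   [Biostrings::RNAStringSet] of length 1).
#' @param candidates named character vector or [Biostrings::XStringSet] of
#'   candidate transcript sequences (e.g. the downregulated mRNAs).
#' @param config a [ScanConfig-class].
#' @return data.frame of hits: `mirna_id`, `target_id`, `seed_length`,
#'   `mirna_start`, `mirna_end`, `target_start`, `target_end`, `nfe`
#'   (kcal/mol), `temperature`, `strong` (`nfe <= strongNfe`); attributes
#'   `n_candidates` and `n_hits`.
#' @export
screenTargets <- function(mirna, candidates, config = ScanConfig()) {
    if (is(mirna, "XStringSet")) {
        stopifnot(length(mirna) == 1L)
        mirna <- setNames(as.character(mirna), names(mirna))
    }
    mirnaId <- if (!is.null(names(mirna))) names(mirna)[1L] else "mirna"
    mirnaSeq <- as.character(mirna)[1L]
    if (is(candidates, "XStringSet"))
        candidates <- setNames(as.character(candidates), names(candidates))
    if (length(candidates) == 0L) {
        warning("empty candidate set")
        out <- data.frame(mirna_id = character(0), target_id = character(0),
                          seed_length = integer(0), mirna_start = integer(0),
                          mirna_end = integer(0), target_start = integer(0),
                          target_end = integer(0), nfe = numeric(0),
                          temperature = numeric(0), strong = logical(0))
        attr(out, "n_candidates") <- 0L; attr(out, "n_hits") <- 0L
        return(out)
    }
    if (is.null(names(candidates)))
        names(candidates) <- sprintf("candidate%04d", seq_along(candidates))
    rows <- list()
    for (id in names(candidates)) {
        hit <- longestComplementSeed(mirnaSeq, candidates[[id]], config)
        if (hit$seed_length < config@minSeed) next
        mi <- start(hit$mirna_span); mj <- end(hit$mirna_span)
        ti <- start(hit$target_span); tj <- end(hit$target_span)
        nfe <- if (hit$has_gu) NA_real_ else {
            mW <- substr(mirnaSeq, mi, mj)
            tW <- substr(candidates[[id]], ti, tj)
            duplexEnergy(mW, tW, config@temperature, config@nnParameterSet)
        }
        rows[[length(rows) + 1L]] <- data.frame(
            mirna_id = mirnaId, target_id = id,
            seed_length = hit$seed_length, mirna_start = mi, mirna_end = mj,
            target_start = ti, target_end = tj, nfe = nfe,
            temperature = config@temperature,
            strong = !is.na(nfe) & nfe <= config@strongNfe,
            stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, rows) else data.frame(
        mirna_id = character(0), target_id = character(0),
        seed_length = integer(0), mirna_start = integer(0),
        mirna_end = integer(0), target_start = integer(0),
        target_end = integer(0), nfe = numeric(0), temperature = numeric(0),
        strong = logical(0))
    if (nrow(out))
        out <- out[order(-out$seed_length, out$nfe, out$target_id,
                         na.last = TRUE), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_candidates") <- length(candidates)
    attr(out, "n_hits") <- nrow(out)
    out
}
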