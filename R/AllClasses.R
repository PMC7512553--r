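#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- queryHits subjectHits
#' @importFrom IRanges IRanges Views viewMeans viewMaxs slice reduce width start end
#' @importFrom GenomicRanges GRanges granges seqnames strand strand<- coverage findOverlaps pintersect
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<- seqinfo Seqinfo
#' @importFrom Biostrings DNAStringSet RNAString RNAStringSet reverseComplement writeXStringSet readDNAStringSet
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowRanges
#' @importFrom stats median rnbinom rpois pnorm p.adjust dnbinom dpois quantile setNames var
#' @importFrom utils read.delim write.table
NULL

## The three diapause-inducing / control bacteria and the two generations of
## the intergenerational feeding design.
.DEFAULT_BACTERIA <- c("OP50", "PAO1", "MST1")
.DEFAULT_GENERATIONS <- c("F1", "F2")

## Closed biotype vocabulary for annotation features.  Unknown types map to
## "other" (with a warning) on import.
.BIOTYPES <- c("miRNA", "pre_miRNA", "rRNA", "piRNA_21ur", "tRNA",
               "pseudogene", "lincRNA", "snoRNA", "snRNA", "coding_exon",
               "intron", "five_prime_UTR", "three_prime_UTR", "other")

## Biotypes that count as "annotated sRNAs" for the known/exact-match rule.
.SRNA_BIOTYPES <- c("miRNA", "pre_miRNA", "piRNA_21ur", "tRNA",
                    "snoRNA", "snRNA")

#' Study design for the two-generation pathogen feeding experiment
#'
#' Describes the factorial layout of the sequencing study the pipeline
#' analyses: a control bacterium plus pathogenic bacteria, fed to worms for
#' consecutive generations, with replicate libraries per bacterium x
#' generation cell.  The default design is E. coli OP50 (control) and the two
#' mild pathogens P. aeruginosa PAO1 and S. enterica MST1, generations F1 and
#' F2, three biological replicates each, yielding the four pathogen
#' contrasts (PAO1_F1, PAO1_F2, MST1_F1, MST1_F2), each against OP50 of the
#' same generation.
#'
#' @slot bacteria character vector; first element is the control.
#' @slot generations character vector of generation labels.
#' @slot replicates integer; replicate libraries per condition (>= 2).
#' @slot seed integer; base RNG seed for simulations tied to this design.
#' @exportClass StudyDesign
setClass("StudyDesign", representation(
    bacteria = "character",
    generations = "character",
    replicates = "integer",
    seed = "integer"
))

setValidity("StudyDesign", function(object) {
    msg <- NULL
    if (length(object@bacteria) < 2L)
        msg <- c(msg, "need a control bacterium plus at least one pathogen")
    if (anyDuplicated(object@bacteria))
        msg <- c(msg, "duplicated bacterium labels")
    if (length(object@generations) < 1L)
        msg <- c(msg, "need at least one generation")
    if (length(object@replicates) != 1L || is.na(object@replicates) ||
        object@replicates < 2L)
        msg <- c(msg, "replicates_per_condition must be a single integer >= 2")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "seed must be a single integer")
    if (is.null(msg)) TRUE else msg
})

#' @param bacteria character; bacterium labels, control first.
#' @param generations character; generation labels.
#' @param replicates integer; replicate libraries per condition.
#' @param seed integer; base RNG seed.
#' @return `StudyDesign()` returns a StudyDesign object.
#' @examples
#' design <- StudyDesign()
#' sampleSheet(design)
#' designContrasts(design)
#' @rdname StudyDesign-class
#' @export
StudyDesign <- function(bacteria = .DEFAULT_BACTERIA,
                        generations = .DEFAULT_GENERATIONS,
                        replicates = 3L, seed = 1L) {
    new("StudyDesign", bacteria = as.character(bacteria),
        generations = as.character(generations),
        replicates = as.integer(replicates), seed = as.integer(seed))
}

#' @rdname StudyDesign-class
#' @param object,design a StudyDesign.
#' @export
setGeneric("controlBacterium", function(design) standardGeneric("controlBacterium"))

#' @rdname StudyDesign-class
#' @export
setMethod("controlBacterium", "StudyDesign", function(design) design@bacteria[1L])

#' @rdname StudyDesign-class
#' @export
setGeneric("pathogens", function(design) standardGeneric("pathogens"))

#' @rdname StudyDesign-class
#' @export
setMethod("pathogens", "StudyDesign", function(design) design@bacteria[-1L])

#' @rdname StudyDesign-class
#' @export
setGeneric("replicatesPerCondition", function(design) standardGeneric("replicatesPerCondition"))

#' @rdname StudyDesign-class
#' @export
setMethod("replicatesPerCondition", "StudyDesign", function(design) design@replicates)

#' @describeIn StudyDesign-class sample sheet: one row per library with
#'   columns `sample_id`, `bacterium`, `generation`, `replicate`.
#' @export
setGeneric("sampleSheet", function(design) standardGeneric("sampleSheet"))

#' @rdname StudyDesign-class
#' @export
setMethod("sampleSheet", "StudyDesign", function(design) {
    grid <- expand.grid(replicate = seq_len(design@replicates),
                        generation = design@generations,
                        bacterium = design@bacteria,
                        stringsAsFactors = FALSE)
    grid <- grid[, c("bacterium", "generation", "replicate")]
    grid$sample_id <- sprintf("%s_%s_r%d", grid$bacterium, grid$generation,
                              grid$replicate)
    grid[, c("sample_id", "bacterium", "generation", "replicate")]
})

#' @describeIn StudyDesign-class the pathogen contrasts: each pathogen x
#'   generation cell against the control bacterium of the same generation.
#'   Returns a data.frame with columns `contrast_id`, `bacterium`,
#'   `generation`, `control`.
#' @export
setGeneric("designContrasts", function(design) standardGeneric("designContrasts"))

#' @rdname StudyDesign-class
#' @export
setMethod("designContrasts", "StudyDesign", function(design) {
    grid <- expand.grid(generation = design@generations,
                        bacterium = pathogens(design),
                        stringsAsFactors = FALSE)
    data.frame(contrast_id = sprintf("%s_%s", grid$bacterium, grid$generation),
               bacterium = grid$bacterium, generation = grid$generation,
               control = controlBacterium(design),
               stringsAsFactors = FALSE)
})

setMethod("show", "StudyDesign", function(object) {
    cat("StudyDesign:", length(object@bacteria), "bacteria x",
        length(object@generations), "generations x",
        object@replicates, "replicates\n")
    cat("  control :", controlBacterium(object), "\n")
    cat("  pathogens:", paste(pathogens(object), collapse = ", "), "\n")
    cat("  contrasts:", paste(designContrasts(object)$contrast_id,
                              collapse = ", "), "\n")
})

#' Strand-specific per-base coverage over a set of contigs
#'
#' Holds one run-length-encoded depth vector per contig and strand, as
#' produced by [poolCoverage()] from pooled alignment records.  Depth on each
#' strand counts the records on that strand whose span covers the base.
#'
#' @slot plus,minus [IRanges::RleList] of per-base depths, one element per
#'   contig, equal lengths and names on both strands.
#' @exportClass StrandedCoverage
setClass("StrandedCoverage", representation(
    plus = "RleList", minus = "RleList"
))

setValidity("StrandedCoverage", function(object) {
    msg <- NULL
    if (!identical(names(object@plus), names(object@minus)))
        msg <- c(msg, "plus and minus tracks must cover the same contigs")
    if (!identical(lengths(object@plus), lengths(object@minus)))
        msg <- c(msg, "plus and minus tracks must have equal contig lengths")
    if (any(vapply(object@plus, function(x) min(x) < 0, logical(1))) ||
        any(vapply(object@minus, function(x) min(x) < 0, logical(1))))
        msg <- c(msg, "depth must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' @rdname StrandedCoverage-class
#' @param x a StrandedCoverage.
#' @param strand `"+"` or `"-"`.
#' @return `coverageTrack()` returns the [IRanges::RleList] for one strand.
#' @export
coverageTrack <- function(x, strand = c("+", "-")) {
    strand <- match.arg(strand)
    if (strand == "+") x@plus else x@minus
}

setMethod("show", "StrandedCoverage", function(object) {
    cat("StrandedCoverage over", length(object@plus), "contig(s):",
        paste(names(object@plus), collapse = ", "), "\n")
    tot <- sum(vapply(object@plus, function(x) sum(as.numeric(x)), numeric(1))) +
        sum(vapply(object@minus, function(x) sum(as.numeric(x)), numeric(1)))
    cat("  total covered base-reads:", tot, "\n")
})

#' Configuration of the miRNA target scan
#'
#' Bundles the tunables of the seed-complementarity search and the duplex
#' energy model: the reportable seed-length window (the scan enumerates
#' seeds above the tool default of 8 nt, reports hits with seed >= `minSeed`,
#' and caps seeds at `maxSeed`), the hybridization temperature, and whether
#' G-U wobble pairs may extend a seed.
#'
#' @slot minSeed integer; minimum seed length (contiguous perfect
#'   complementarity) for a reported hit.  Default 12.
#' @slot maxSeed integer; cap on the reported seed length.  Default 20.
#' @slot defaultSeed integer; the scanner's baseline seed length (8), kept
#'   for reference; must be <= minSeed.
#' @slot temperature numeric; temperature in degrees Celsius for the energy
#'   model.  Default 20, the temperature at which the experiments modelled
#'   here are performed.
#' @slot allowGU logical; if TRUE, G-U wobble pairs may occur inside a seed.
#'   Default FALSE (strict Watson-Crick complementarity).
#' @slot nnParameterSet character; identifier of the shipped nearest-neighbor
#'   parameter table (see [nnParameters()]).
#' @slot strongNfe numeric; free-energy threshold (kcal/mol) below which a
#'   hit is flagged "strong".  Default -10.
#' @exportClass ScanConfig
setClass("ScanConfig", representation(
    minSeed = "integer", maxSeed = "integer", defaultSeed = "integer",
    temperature = "numeric", allowGU = "logical",
    nnParameterSet = "character", strongNfe = "numeric"
))

setValidity("ScanConfig", function(object) {
    msg <- NULL
    if (!(object@defaultSeed <= object@minSeed && object@minSeed <= object@maxSeed))
        msg <- c(msg, "need defaultSeed <= minSeed <= maxSeed")
    if (object@defaultSeed < 2L)
        msg <- c(msg, "defaultSeed must be >= 2")
    if (is.null(msg)) TRUE else msg
})

#' @param minSeed,maxSeed,defaultSeed,temperature,allowGU,nnParameterSet,strongNfe
#'   see slot documentation.
#' @return `ScanConfig()` returns a ScanConfig object.
#' @examples
#' ScanConfig()
#' @rdname ScanConfig-class
#' @export
ScanConfig <- function(minSeed = 12L, maxSeed = 20L, defaultSeed = 8L,
                       temperature = 20, allowGU = FALSE,
                       nnParameterSet = "xia1998", strongNfe = -10) {
    new("ScanConfig", minSeed = as.integer(minSeed),
        maxSeed = as.integer(maxSeed), defaultSeed = as.integer(defaultSeed),
        temperature = as.numeric(temperature), allowGU = as.logical(allowGU),
        nnParameterSet = as.character(nnParameterSet),
        strongNfe = as.numeric(strongNfe))
}

setMethod("show", "ScanConfig", function(object) {
    cat("ScanConfig: seed in [", object@minSeed, ",", object@maxSeed,
        "] (default ", object@defaultSeed, "), T = ", object@temperature,
        " degC, GU ", if (object@allowGU) "allowed" else "excluded",
        ", params ", object@nnParameterSet, "\n", sep = "")
})

#' Shared and condition-specific differential features across contrasts
#'
#' Result of the cross-condition set logic ([buildVenn()]): for one direction
#' of change, which contrasts each differential feature belongs to, and the
#' derived cells of interest -- features shared by all four pathogen x
#' generation contrasts, bacterium-specific features (both generations of
#' exactly one pathogen), and generation-specific features (a single
#' contrast only).
#'
#' @slot direction `"up"` or `"down"`.
#' @slot contrasts character; contrast ids the report spans.
#' @slot membership named list; for each differential feature, the character
#'   vector of contrasts in which it is called in this direction.
#' @slot sharedAll character; features present in every contrast.
#' @slot bacteriumSpecific character; features in both generations of exactly
#'   one pathogen and nowhere else.
#' @slot generationSpecific character; features in exactly one contrast.
#' @exportClass SharedFeatureReport
setClass("SharedFeatureReport", representation(
    direction = "character", contrasts = "character", membership = "list",
    sharedAll = "character", bacteriumSpecific = "character",
    generationSpecific = "character"
))

setMethod("show", "SharedFeatureReport", function(object) {
    cat("SharedFeatureReport (", object@direction, "): ",
        length(object@membership), " DE feature(s) across ",
        length(object@contrasts), " contrasts\n", sep = "")
    cat("  shared in all contrasts   :", length(object@sharedAll), "\n")
    cat("  bacterium-specific        :", length(object@bacteriumSpecific), "\n")
    cat("  generation-specific       :", length(object@generationSpecific), "\n")
})

#' @rdname SharedFeatureReport-class
#' @param x a SharedFeatureReport.
#' @return `sharedAll()`, `bacteriumSpecific()` and `generationSpecific()`
#'   return character vectors of feature ids; `vennMembership()` the named
#'   list of per-feature contrast memberships.
#' @export
sharedAll <- function(x) x@sharedAll

#' @rdname SharedFeatureReport-class
#' @export
bacteriumSpecific <- function(x) x@bacteriumSpecific

#' @rdname SharedFeatureReport-class
#' @export
generationSpecific <- function(x) x@generationSpecific

#' @rdname SharedFeatureReport-class
#' @export
vennMembership <- function(x) x@membership
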