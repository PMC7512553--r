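## Readers and writers for the on-disk formats the pipeline touches.
## SAM is consumed through Rsamtools/GenomicAlignments, GFF3 and BED6
## through rtracklayer; the internal model is always a GRanges (1-based,
## closed intervals, the Bioconductor convention).

## GFF3 "type" column -> closed biotype vocabulary.  Unknown types fall
## back to the feature's `biotype` attribute, then to "other" (warned).
.BIOTYPE_MAP <- c(
    miRNA = "miRNA", miRNA_primary_transcript = "pre_miRNA",
    pre_miRNA = "pre_miRNA", rRNA = "rRNA", rRNA_gene = "rRNA",
    piRNA = "piRNA_21ur", piRNA_21ur = "piRNA_21ur", tRNA = "tRNA",
    pseudogene = "pseudogene", lincRNA = "lincRNA", lnc_RNA = "lincRNA",
    snoRNA = "snoRNA", snRNA = "snRNA", exon = "coding_exon",
    coding_exon = "coding_exon", CDS = "coding_exon", intron = "intron",
    five_prime_UTR = "five_prime_UTR", three_prime_UTR = "three_prime_UTR",
    other = "other")

#' Read strand-aware alignment records
#'
#' Reads mapped single-end alignments from SAM (via an on-the-fly BAM
#' conversion and [GenomicAlignments::readGAlignments()]; the aligned span
#' is the reference-consuming extent of the CIGAR) or from a 6-column BED
#' dialect.  Unmapped SAM records are excluded; their count is attached as
#' attribute `skipped_unmapped` and reported via a message.  Records are
#' returned coordinate-sorted within contig.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"sam"` or `"bed6"`.
#' @return GRanges with a `qname` metadata column and attribute
#'   `skipped_unmapped` (SAM only).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("ctg1\t99\t135\tr1\t0\t+", bed)
#' readAlignments(bed)
#' @export
readAlignments <- function(path, format = c("auto", "sam", "bed6")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    if (format == "auto") {
        format <- switch(tolower(tools::file_ext(path)),
                         sam = "sam", bed = "bed6",
                         stop("cannot guess format of '", path,
                              "'; pass format="))
    }
    if (format == "sam") .readSam(path) else .readBed6(path)
}

.readSam <- function(path) {
    bam <- tryCatch(
        Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                         indexDestination = FALSE),
        error = function(e) stop("malformed SAM '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    on.exit(unlink(bam))
    # samtools silently drops unparseable records; detect and report them
    lines <- readLines(path)
    isRec <- !startsWith(lines, "@") & nzchar(lines)
    nParsed <- Rsamtools::countBam(bam)$records
    if (nParsed < sum(isRec)) {
        bad <- which(isRec & lengths(strsplit(lines, "\t")) < 11L)
        stop("malformed SAM '", path, "': parse error at line ",
             if (length(bad)) bad[1L] else "(unknown)", call. = FALSE)
    }
    ga <- GenomicAlignments::readGAlignments(
        bam, param = Rsamtools::ScanBamParam(what = "qname"))
    gr <- granges(ga)
    mcols(gr)$qname <- mcols(ga)$qname
    nUnmapped <- Rsamtools::countBam(
        bam, param = Rsamtools::ScanBamParam(
            flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)))$records
    if (nUnmapped > 0)
        message("skipped ", nUnmapped, " unmapped record(s) in ", path)
    gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
    attr(gr, "skipped_unmapped") <- nUnmapped
    gr
}

.readBed6 <- function(path) {
    if (file.size(path) == 0L) {
        gr <- GRanges()
        mcols(gr)$qname <- character(0)
        attr(gr, "skipped_unmapped") <- 0L
        return(gr)
    }
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e) stop("malformed BED6 '", path, "': ",
                                            conditionMessage(e), call. = FALSE))
    mcols(gr) <- DataFrame(qname = if (!is.null(mcols(gr)$name))
        mcols(gr)$name else sprintf("read%06d", seq_along(gr)))
    gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
    attr(gr, "skipped_unmapped") <- 0L
    gr
}

#' Write alignment records as minimal SAM
#'
#' Emits a coordinate-sorted SAM file (header with `@SQ` lines from the
#' seqlengths, one mapped ungapped single-end record per range, sequence and
#' quality omitted).
#'
#' @param aln GRanges with seqlengths and (optionally) a `qname` column.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeAlignmentsSam <- function(aln, path) {
    sl <- seqlengths(aln)
    if (any(is.na(sl))) stop("alignments must carry seqlengths to write SAM")
    aln <- BiocGenerics::sort(aln, ignore.strand = TRUE)
    qn <- mcols(aln)$qname
    if (is.null(qn)) qn <- sprintf("read%06d", seq_along(aln))
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl))
    flag <- ifelse(as.character(strand(aln)) == "-", 16L, 0L)
    recs <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                    qn, flag, as.character(seqnames(aln)), start(aln),
                    width(aln))
    writeLines(c(header, recs), path)
    invisible(path)
}

#' Write alignment records as BED6
#'
#' @param aln GRanges with an optional `qname` column (becomes the BED name).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeAlignmentsBed <- function(aln, path) {
    gr <- granges(aln)
    qn <- mcols(aln)$qname
    mcols(gr)$name <- if (is.null(qn)) sprintf("read%06d", seq_along(aln)) else qn
    mcols(gr)$score <- 0L
    rtracklayer::export(BiocGenerics::sort(gr, ignore.strand = TRUE), path,
                        format = "BED")
    invisible(path)
}

#' Read a reference annotation from GFF3
#'
#' Imports features and maps the GFF type column onto the closed biotype
#' vocabulary (`miRNA`, `pre_miRNA`, `rRNA`, `piRNA_21ur`, `tRNA`,
#' `pseudogene`, `lincRNA`, `snoRNA`, `snRNA`, `coding_exon`, `intron`,
#' `five_prime_UTR`, `three_prime_UTR`, `other`); a `biotype` attribute in
#' column 9 takes precedence over the type column, and unknown types map to
#' `other` with a warning.
#'
#' @param path GFF3 file.
#' @return GRanges with metadata columns `feature_id`, `biotype`,
#'   `parent_id`.
#' @export
readAnnotation <- function(path) {
    gr <- tryCatch(rtracklayer::import(path, format = "GFF3"),
                   error = function(e) stop("invalid GFF3 '", path, "': ",
                                            conditionMessage(e), call. = FALSE))
    m <- mcols(gr)
    typ <- as.character(m$type)
    bt <- if (!is.null(m$biotype)) as.character(m$biotype) else rep(NA, length(gr))
    bt[is.na(bt)] <- unname(.BIOTYPE_MAP[typ[is.na(bt)]])
    if (anyNA(bt)) {
        warning("unknown feature type(s) mapped to 'other': ",
                paste(unique(typ[is.na(bt)]), collapse = ", "))
        bt[is.na(bt)] <- "other"
    }
    bad <- !(bt %in% .BIOTYPES)
    if (any(bad)) {
        warning("unknown biotype(s) mapped to 'other': ",
                paste(unique(bt[bad]), collapse = ", "))
        bt[bad] <- "other"
    }
    fid <- if (!is.null(m$ID)) as.character(m$ID) else
        sprintf("feature%06d", seq_along(gr))
    parent <- if (!is.null(m$Parent)) {
        p <- as(m$Parent, "CharacterList")
        ifelse(lengths(p) > 0, vapply(p, `[`, "", 1L), NA_character_)
    } else rep(NA_character_, length(gr))
    mcols(gr) <- DataFrame(feature_id = fid, biotype = bt, parent_id = parent)
    gr
}

#' Write an annotation GRanges as GFF3
#'
#' Inverse of [readAnnotation()]: emits one line per feature with the
#' biotype as the type column and `ID`/`Parent`/`biotype` attributes, so a
#' write-read round trip reproduces the internal feature set.
#'
#' @param annotation GRanges with `feature_id`, `biotype`, `parent_id`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeAnnotation <- function(annotation, path) {
    gr <- granges(annotation)
    m <- mcols(annotation)
    mcols(gr)$source <- "tpscan"
    mcols(gr)$type <- m$biotype
    mcols(gr)$ID <- m$feature_id
    mcols(gr)$biotype <- m$biotype
    hasParent <- !is.na(m$parent_id)
    parent <- as(as.list(ifelse(hasParent, m$parent_id, "")), "CharacterList")
    parent[!hasParent] <- as(list(character(0)), "CharacterList")
    mcols(gr)$Parent <- parent
    rtracklayer::export(gr, path, format = "GFF3")
    invisible(path)
}

#' Write transcriptional peaks as a custom GFF3
#'
#' One line per peak, sorted by contig then start, with the peak id and its
#' mean/max coverage carried as attributes.  Zero peaks yield a valid
#' header-only GFF3.
#'
#' @param peaks GRanges from [callPeaks()] (metadata columns `tp_id`,
#'   `mean_coverage`, `max_coverage`).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeTpGff <- function(peaks, path) {
    o <- order(as.character(seqnames(peaks)), start(peaks))
    peaks <- peaks[o]
    if (length(peaks) == 0L) {
        writeLines("##gff-version 3", path)
        return(invisible(path))
    }
    gr <- granges(peaks)
    n <- length(gr)
    mcols(gr) <- DataFrame(
        source = rep("tpscan", n),
        type = rep("transcriptional_peak", n),
        ID = as.character(mcols(peaks)$tp_id),
        mean_coverage = sprintf("%.4f", mcols(peaks)$mean_coverage),
        max_coverage = sprintf("%.4f", mcols(peaks)$max_coverage))
    rtracklayer::export(gr, path, format = "GFF3")
    invisible(path)
}

#' Read transcriptional peaks from a GFF3 written by [writeTpGff()]
#'
#' @param path GFF3 file.
#' @return GRanges with `tp_id`, `mean_coverage`, `max_coverage`.
#' @export
readTpGff <- function(path) {
    gr <- rtracklayer::import(path, format = "GFF3")
    m <- mcols(gr)
    mcols(gr) <- DataFrame(tp_id = as.character(m$ID),
                           mean_coverage = as.numeric(m$mean_coverage),
                           max_coverage = as.numeric(m$max_coverage))
    gr
}

#' Read and write the sample sheet
#'
#' Tab-separated, columns `sample_id`, `bacterium`, `generation`,
#' `replicate`.
#'
#' @param path TSV file.
#' @return `readSampleSheetTsv()` returns a data.frame.
#' @export
readSampleSheetTsv <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "bacterium", "generation", "replicate")
    if (!all(need %in% names(df)))
        stop("sample sheet must have columns: ", paste(need, collapse = ", "))
    df
}

#' @param sheet data.frame as returned by [sampleSheet()].
#' @rdname readSampleSheetTsv
#' @export
writeSampleSheetTsv <- function(sheet, path) {
    write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write count matrices as TSV
#'
#' Features in rows (first column `feature_id`), samples in columns.
#'
#' @param path TSV file.
#' @return `readCountsTsv()` returns an integer matrix with feature
#'   rownames.
#' @export
readCountsTsv <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- df[[1L]]
    m
}

#' @param counts integer matrix, features x samples.
#' @rdname readCountsTsv
#' @export
writeCountsTsv <- function(counts, path) {
    df <- data.frame(feature_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a contig-length table (FASTA index dialect)
#'
#' Accepts a two-or-more-column TSV whose first two columns are contig name
#' and length (the layout of a `samtools faidx` `.fai` file).
#'
#' @param path file path.
#' @return named integer vector of contig lengths.
#' @export
readContigLengths <- function(path) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    setNames(as.integer(df[[2L]]), as.character(df[[1L]]))
}
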