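## Simplified in-package negative-binomial differential expression with two
## estimators and a consensus decision rule.  Method A is a Wald test on
## median-of-ratios-normalized counts (DESeq-style normalization); method B
## is a conditional exact NB test on TMM-equalized pseudo-counts
## (edgeR-style normalization).  A feature is called differential only when
## |log2 fold change| > 1 AND the BH-adjusted method-A p-value is < 0.05
## AND the raw method-B p-value is < 0.05 (down calls symmetric with
## log2fc < -1).  The package claims this decision rule, not numerical
## identity with the published implementations.

#' Median-of-ratios size factors
#'
#' Per-library size factor: the median, over features with strictly
#' positive counts in every library, of the ratio of the library's count to
#' the feature's geometric mean across libraries.  If no feature is
#' positive everywhere, falls back to library-size ratios (normalized to
#' geometric mean 1) with a warning.
#'
#' @param counts integer matrix, features x libraries.
#' @return positive numeric vector of size factors, one per library.
#' @examples
#' m <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
#' sizeFactorsMedianOfRatios(m)
#' @export
sizeFactorsMedianOfRatios <- function(counts) {
    counts <- as.matrix(counts)
    allPos <- rowSums(counts <= 0) == 0
    if (!any(allPos)) {
        warning("no feature with all-positive counts; ",
                "falling back to library-size ratios")
        ls <- colSums(counts)
        if (any(ls == 0)) stop("library with zero total counts")
        return(ls / exp(mean(log(ls))))
    }
    lx <- log(counts[allPos, , drop = FALSE])
    ref <- rowMeans(lx)
    sf <- apply(lx, 2L, function(col) exp(median(col - ref)))
    unname(sf)
}

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Simplified TMM: per-library proportions are compared to a reference
#' library (the one whose upper-quartile proportion is closest to the
#' mean); the factor is 2 to the mean of the log2 ratios (M-values) after
#' trimming the most extreme `logratioTrim` fraction of M from each tail
#' and `sumTrim` of the average abundance (A) from each tail.  Factors are
#' renormalized to geometric mean 1.
#'
#' @param counts integer matrix, features x libraries.
#' @param logratioTrim fraction of M trimmed from each tail (default 0.30).
#' @param sumTrim fraction of A trimmed from each tail (default 0.05).
#' @param refColumn optional integer; force the reference library.
#' @return positive numeric vector of TMM factors, geometric mean 1.
#' @export
tmmFactors <- function(counts, logratioTrim = 0.30, sumTrim = 0.05,
                       refColumn = NULL) {
    counts <- as.matrix(counts)
    ls <- colSums(counts)
    if (any(ls == 0)) {
        bad <- colnames(counts)[ls == 0]
        if (is.null(bad)) bad <- which(ls == 0)
        stop("all-zero library: ", paste(bad, collapse = ", "))
    }
    p <- sweep(counts, 2L, ls, `/`)
    if (is.null(refColumn)) {
        uq <- apply(p, 2L, quantile, probs = 0.75)
        refColumn <- which.min(abs(uq - mean(uq)))
    }
    f <- vapply(seq_len(ncol(counts)), function(j) {
        if (j == refColumn) return(1)
        ok <- p[, j] > 0 & p[, refColumn] > 0
        if (!any(ok)) return(1)
        M <- log2(p[ok, j] / p[ok, refColumn])
        A <- 0.5 * log2(p[ok, j] * p[ok, refColumn])
        keep <- M >= quantile(M, logratioTrim) &
                M <= quantile(M, 1 - logratioTrim) &
                A >= quantile(A, sumTrim) &
                A <= quantile(A, 1 - sumTrim)
        if (!any(keep)) keep <- rep(TRUE, length(M))
        2^mean(M[keep])
    }, numeric(1))
    unname(f / exp(mean(log(f))))
}

#' Per-feature negative-binomial dispersion
#'
#' Method-of-moments estimator pooled across conditions:
#' `phi = max(0, (s2 - m) / m^2)` where `s2` is the replicate variance
#' pooled over condition groups and `m` the grand mean, both on
#' size-factor-normalized counts.  `method = "shrunken"` (default) shrinks
#' each feature's moment estimate toward the mean-expression trend (10
#' abundance bins) with weight proportional to the residual degrees of
#' freedom against a prior weight of `priorDf`.
#'
#' @param counts integer matrix, features x libraries.
#' @param groups factor of condition labels, one per library; every level
#'   needs >= 2 replicates.
#' @param method `"shrunken"` or `"moments_pooled"`.
#' @param sizeFactors optional per-library size factors (default all 1).
#' @param priorDf prior degrees of freedom for shrinkage (default 10).
#' @return numeric vector of per-feature dispersions (>= 0).
#' @export
estimateDispersion <- function(counts, groups,
                               method = c("shrunken", "moments_pooled"),
                               sizeFactors = NULL, priorDf = 10) {
    method <- match.arg(method)
    counts <- as.matrix(counts)
    groups <- as.factor(groups)
    stopifnot(length(groups) == ncol(counts))
    nPer <- table(groups)
    if (any(nPer < 2L))
        stop("cannot estimate dispersion with a single replicate in group(s): ",
             paste(names(nPer)[nPer < 2L], collapse = ", "))
    if (is.null(sizeFactors)) sizeFactors <- rep(1, ncol(counts))
    q <- sweep(counts, 2L, sizeFactors, `/`)
    residDf <- sum(nPer - 1L)
    ssq <- 0
    for (g in levels(groups)) {
        cols <- which(groups == g)
        mg <- rowMeans(q[, cols, drop = FALSE])
        ssq <- ssq + rowSums((q[, cols, drop = FALSE] - mg)^2)
    }
    s2 <- ssq / residDf
    m <- rowMeans(q)
    phi <- ifelse(m > 0, pmax(0, (s2 - m) / m^2), 0)
    if (method == "moments_pooled") return(phi)
    # shrink toward the abundance trend
    bins <- cut(rank(m, ties.method = "first"),
                breaks = min(10L, max(1L, nrow(counts))), labels = FALSE)
    trend <- stats::ave(phi, bins, FUN = mean)
    (residDf * phi + priorDf * trend) / (residDf + priorDf)
}

#' Negative-binomial Wald test (method A)
#'
#' Log2 fold change from size-factor-normalized group means with a 0.5
#' pseudo-count; the standard error follows the NB variance model
#' `Var(K_ij) = sf_j * mu + phi * (sf_j * mu)^2` propagated to the log2
#' means by the delta method; two-sided p-value from the standard normal.
#' Features with zero counts on both sides get `log2fc = 0, p = 1`.
#'
#' @param counts integer matrix, features x libraries.
#' @param controlCols,treatedCols column indices (or names) of the two
#'   groups; each needs >= 2 replicates.
#' @param sizeFactors per-library size factors
#'   ([sizeFactorsMedianOfRatios()]).
#' @param phi per-feature dispersion(s), recycled.
#' @return data.frame: `mean_control`, `mean_treated` (normalized),
#'   `log2fc`, `se`, `stat`, `p`.
#' @export
nbWaldTest <- function(counts, controlCols, treatedCols, sizeFactors, phi) {
    counts <- as.matrix(counts)
    if (is.character(controlCols)) controlCols <- match(controlCols, colnames(counts))
    if (is.character(treatedCols)) treatedCols <- match(treatedCols, colnames(counts))
    stopifnot(length(controlCols) >= 2L, length(treatedCols) >= 2L)
    phi <- rep(phi, length.out = nrow(counts))
    q <- sweep(counts, 2L, sizeFactors, `/`)
    mC <- rowMeans(q[, controlCols, drop = FALSE])
    mT <- rowMeans(q[, treatedCols, drop = FALSE])
    lfc <- log2((mT + 0.5) / (mC + 0.5))
    varLog2Mean <- function(m, cols) {
        mu <- m + 0.5  # pseudo-count stabilizes zero-count groups
        v <- outer(mu, 1 / sizeFactors[cols]) + phi * mu^2
        rowSums(v) / length(cols)^2 / (mu^2 * log(2)^2)
    }
    se <- sqrt(varLog2Mean(mC, controlCols) + varLog2Mean(mT, treatedCols))
    stat <- ifelse(se > 0, lfc / se, 0)
    p <- 2 * pnorm(-abs(stat))
    zero <- mC == 0 & mT == 0
    lfc[zero] <- 0; stat[zero] <- 0; p[zero] <- 1
    data.frame(mean_control = mC, mean_treated = mT, log2fc = lfc,
               se = se, stat = stat, p = pmin(1, p),
               row.names = rownames(counts))
}

## Conditional exact NB p-value for one feature: probability, under equal
## means and common dispersion, of group-sum splits at least as improbable
## as the observed one, given the total.
.exactNbSplitP <- function(sA, sB, nA, nB, phi) {
    s <- sA + sB
    if (s == 0) return(1)
    mu <- s / (nA + nB)
    y <- 0:s
    if (phi <= 0) {
        la <- dpois(y, nA * mu, log = TRUE)
        lb <- dpois(s - y, nB * mu, log = TRUE)
    } else {
        la <- dnbinom(y, mu = nA * mu, size = nA / phi, log = TRUE)
        lb <- dnbinom(s - y, mu = nB * mu, size = nB / phi, log = TRUE)
    }
    lp <- la + lb
    lp <- lp - max(lp)
    pr <- exp(lp)
    pobs <- pr[sA + 1L]
    min(1, sum(pr[pr <= pobs * (1 + 1e-10)]) / sum(pr))
}

#' Conditional exact negative-binomial test (method B)
#'
#' Counts are first equalized to a common effective library size
#' (library size times TMM factor): each library's counts are scaled to the
#' geometric-mean effective size and rounded ("pseudo-counts").  For each
#' feature the two group sums are then compared with a conditional exact
#' test: given the total, the probability of all splits whose probability
#' under NB (equal means, common dispersion `phi`) does not exceed the
#' observed split's.  With `phi = 0` this reduces to an exact binomial
#' split test.
#'
#' @param counts integer matrix, features x libraries.
#' @param controlCols,treatedCols column indices (or names) of the groups.
#' @param effectiveLibSizes per-library effective sizes (library size x TMM
#'   factor); default: column sums times 1.
#' @param phi single common dispersion (>= 0).
#' @return numeric vector of two-sided p-values.
#' @export
nbExactTest <- function(counts, controlCols, treatedCols,
                        effectiveLibSizes = NULL, phi = 0) {
    counts <- as.matrix(counts)
    if (is.character(controlCols)) controlCols <- match(controlCols, colnames(counts))
    if (is.character(treatedCols)) treatedCols <- match(treatedCols, colnames(counts))
    cols <- c(controlCols, treatedCols)
    if (is.null(effectiveLibSizes)) effectiveLibSizes <- colSums(counts)
    eff <- effectiveLibSizes[cols]
    scale <- exp(mean(log(eff))) / eff
    pseudo <- round(sweep(counts[, cols, drop = FALSE], 2L, scale, `*`))
    nA <- length(controlCols); nB <- length(treatedCols)
    sA <- rowSums(pseudo[, seq_len(nA), drop = FALSE])
    sB <- rowSums(pseudo[, nA + seq_len(nB), drop = FALSE])
    vapply(seq_len(nrow(counts)),
           function(i) .exactNbSplitP(sA[i], sB[i], nA, nB, phi),
           numeric(1))
}

#' Consensus differential-expression call
#'
#' Applies the three-part rule: `up` iff `log2fc > lfcThreshold` and
#' BH-adjusted method-A p < `alphaA` and raw method-B p < `alphaB`;
#' `down` symmetric with `log2fc < -lfcThreshold`; otherwise `ns`.
#'
#' @param records data.frame with columns `log2fc`, `padj_a`, `p_b`.
#' @param lfcThreshold log2 fold-change gate (default 1).
#' @param alphaA,alphaB significance gates for the two methods
#'   (defaults 0.05).
#' @return the input with a `call` column (`up`/`down`/`ns`) appended.
#' @examples
#' consensusCall(data.frame(log2fc = c(2, 0.9, 2),
#'                          padj_a = c(0.01, 0.001, 0.06),
#'                          p_b = c(0.01, 0.001, 0.01)))$call
#' @export
consensusCall <- function(records, lfcThreshold = 1, alphaA = 0.05,
                          alphaB = 0.05) {
    need <- c("log2fc", "padj_a", "p_b")
    if (!all(need %in% names(records)))
        stop("records must have columns: ", paste(need, collapse = ", "))
    if (anyNA(records[need]))
        stop("missing method results in consensus input")
    sig <- records$padj_a < alphaA & records$p_b < alphaB
    records$call <- ifelse(sig & records$log2fc > lfcThreshold, "up",
                    ifelse(sig & records$log2fc < -lfcThreshold, "down", "ns"))
    records
}

#' Run one pathogen-vs-control contrast
#'
#' Orchestrates both estimators for a single two-group comparison:
#' median-of-ratios size factors and shrunken dispersions feed the Wald
#' test; TMM-equalized pseudo-counts and the median shrunken dispersion
#' feed the exact test; method-A p-values are BH-adjusted within the
#' contrast, and the consensus rule is applied.
#'
#' @param counts integer matrix, features x libraries (full study).
#' @param sheet sample sheet data.frame covering the columns of `counts`.
#' @param bacterium,generation the pathogen x generation cell to test.
#' @param control control bacterium label (default `"OP50"`).
#' @param lfcThreshold,alphaA,alphaB consensus gates (see
#'   [consensusCall()]).
#' @param dispersionMethod passed to [estimateDispersion()].
#' @return data.frame: `feature_id`, `contrast_id`, `mean_control`,
#'   `mean_treated`, `log2fc`, `p_a`, `padj_a`, `p_b`, `call`.
#' @export
runDeContrast <- function(counts, sheet, bacterium, generation,
                          control = "OP50", lfcThreshold = 1,
                          alphaA = 0.05, alphaB = 0.05,
                          dispersionMethod = "shrunken") {
    counts <- as.matrix(counts)
    ctrlIds <- sheet$sample_id[sheet$bacterium == control &
                               sheet$generation == generation]
    trtIds <- sheet$sample_id[sheet$bacterium == bacterium &
                              sheet$generation == generation]
    if (length(ctrlIds) < 2L || length(trtIds) < 2L)
        stop("contrast needs >= 2 replicates per side")
    sub <- counts[, c(ctrlIds, trtIds), drop = FALSE]
    grp <- factor(rep(c("control", "treated"),
                      c(length(ctrlIds), length(trtIds))))
    sf <- sizeFactorsMedianOfRatios(sub)
    phi <- estimateDispersion(sub, grp, method = dispersionMethod,
                              sizeFactors = sf)
    wald <- nbWaldTest(sub, seq_along(ctrlIds),
                       length(ctrlIds) + seq_along(trtIds), sf, phi)
    tmm <- tryCatch(tmmFactors(sub), error = function(e) rep(1, ncol(sub)))
    pB <- nbExactTest(sub, seq_along(ctrlIds),
                      length(ctrlIds) + seq_along(trtIds),
                      effectiveLibSizes = colSums(sub) * tmm,
                      phi = median(phi))
    res <- data.frame(feature_id = rownames(counts),
                      contrast_id = sprintf("%s_%s", bacterium, generation),
                      mean_control = wald$mean_control,
                      mean_treated = wald$mean_treated,
                      log2fc = wald$log2fc, p_a = wald$p,
                      padj_a = p.adjust(wald$p, method = "BH"),
                      p_b = pB, stringsAsFactors = FALSE,
                      row.names = NULL)
    consensusCall(res, lfcThreshold, alphaA, alphaB)
}

#' Run the consensus DE analysis over every design contrast
#'
#' @param counts integer matrix, features x libraries, or a
#'   SummarizedExperiment from [assembleCountMatrix()].
#' @param design a [StudyDesign]; its contrasts (each pathogen x generation
#'   vs the control of the same generation) are tested with
#'   [runDeContrast()].
#' @param sheet sample sheet; defaults to `sampleSheet(design)` (or the
#'   colData of the SummarizedExperiment).
#' @param ... passed to [runDeContrast()].
#' @return named list of per-contrast data.frames (names = contrast ids).
#' @export
runConsensusDE <- function(counts, design = StudyDesign(), sheet = NULL, ...) {
    if (is(counts, "SummarizedExperiment")) {
        if (is.null(sheet)) sheet <- as.data.frame(colData(counts))
        counts <- assay(counts, "counts")
    }
    if (is.null(sheet)) sheet <- sampleSheet(design)
    contr <- designContrasts(design)
    out <- vector("list", nrow(contr))
    names(out) <- contr$contrast_id
    for (i in seq_len(nrow(contr))) {
        out[[i]] <- runDeContrast(counts, sheet, contr$bacterium[i],
                                  contr$generation[i],
                                  control = contr$control[i], ...)
    }
    out
}
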