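## Independent brute-force oracles.  Each is a deliberately naive
## re-derivation of the quantity it checks, sharing no code with the
## package implementation.

## Per-base scan: maximal runs of depth > threshold, then length/mean
## filters.  Plain loop over bases.
oraclePeaks <- function(depth, threshold = 10, minLen = 17, maxLen = 150,
                        minMean = 10) {
    depth <- as.numeric(depth)
    out <- data.frame(start = integer(0), end = integer(0),
                      mean = numeric(0), max = numeric(0))
    i <- 1L; n <- length(depth)
    while (i <= n) {
        if (depth[i] > threshold) {
            j <- i
            while (j < n && depth[j + 1L] > threshold) j <- j + 1L
            len <- j - i + 1L
            m <- mean(depth[i:j])
            if (len >= minLen && len <= maxLen && m >= minMean)
                out <- rbind(out, data.frame(start = i, end = j, mean = m,
                                             max = max(depth[i:j])))
            i <- j + 1L
        } else i <- i + 1L
    }
    out
}

## Per-base pileup from read intervals (1-based closed).
oraclePileup <- function(starts, ends, contigLength) {
    depth <- integer(contigLength)
    for (k in seq_along(starts)) {
        idx <- starts[k]:ends[k]
        depth[idx] <- depth[idx] + 1L
    }
    depth
}

## O(N*M) interval-scan classifier: same decision cascade as classifyTps,
## computed feature by feature with scalar arithmetic.
oracleClassify <- function(tpStart, tpEnd, tpStrand, feat,
                           srnaBts = srnaBiotypes(), recip = 0.8,
                           sameStrand = TRUE) {
    ovw <- pmax(0L, pmin(tpEnd, feat$end) - pmax(tpStart, feat$start) + 1L)
    hit <- which(ovw > 0L)
    if (length(hit) == 0L)
        return(list(category = "novel", relation = "intergenic",
                    orientation = "n/a"))
    tpW <- tpEnd - tpStart + 1L
    fW <- feat$end - feat$start + 1L
    known <- hit[ovw[hit] / tpW >= recip & ovw[hit] / fW[hit] >= recip &
                 feat$biotype[hit] %in% srnaBts &
                 (!sameStrand | feat$strand[hit] == tpStrand)]
    if (length(known)) {
        b <- known[order(-ovw[known], fW[known], feat$feature_id[known])][1L]
        return(list(category = "known", relation = "exact_srna_match",
                    orientation = if (feat$strand[b] == tpStrand) "sense"
                                  else "antisense"))
    }
    nested <- any(feat$start[hit] <= tpStart & feat$end[hit] >= tpEnd)
    b <- hit[order(-ovw[hit], fW[hit], feat$feature_id[hit])][1L]
    list(category = "partially_novel",
         relation = if (nested) "nested" else "overlapping",
         orientation = if (feat$strand[b] == tpStrand) "sense" else "antisense")
}

## Exhaustive all-substring seed oracle: for decreasing window length L,
## test EVERY miRNA window against EVERY target window for perfect
## antiparallel pairing (O(n*m*L) enumeration; each window is checked with
## a direct per-position pair table lookup).  The reported length is capped
## at maxSeed; among windows of the reported length the one with the
## smallest target start, then smallest miRNA start, wins.
oracleSeed <- function(mirna, target, allowGU = FALSE, maxSeed = 20L) {
    m <- strsplit(gsub("T", "U", toupper(mirna)), "")[[1L]]
    t <- strsplit(gsub("T", "U", toupper(target)), "")[[1L]]
    P <- matrix(FALSE, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                             c("A", "C", "G", "U")))
    P["A", "U"] <- P["U", "A"] <- P["G", "C"] <- P["C", "G"] <- TRUE
    if (allowGU) P["G", "U"] <- P["U", "G"] <- TRUE
    n <- length(m); nt <- length(t)
    windowsAt <- function(L) {
        hits <- NULL
        for (j in seq_len(nt - L + 1L)) {
            for (i in seq_len(n - L + 1L)) {
                if (all(P[cbind(m[i:(i + L - 1L)], t[(j + L - 1L):j])]))
                    hits <- rbind(hits, c(i = i, j = j))
            }
        }
        hits
    }
    for (L in seq(min(n, nt), 1L)) {
        hits <- windowsAt(L)
        if (!is.null(hits)) {
            Lrep <- min(L, maxSeed)
            if (Lrep < L) hits <- windowsAt(Lrep)
            best <- hits[order(hits[, "j"], hits[, "i"])[1L], ]
            return(list(seed_length = Lrep,
                        mirna_start = unname(best["i"]),
                        target_start = unname(best["j"])))
        }
    }
    list(seed_length = 0L, mirna_start = NA_integer_, target_start = NA_integer_)
}

## Benjamini-Hochberg by the textbook formula.
oracleBH <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n)
    out[o] <- pmin(1, adj)
    out
}

## Random RNA string.
randomRna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                               collapse = "")

## Reverse complement on character RNA.
revCompRna <- function(x) {
    chars <- rev(strsplit(x, "")[[1L]])
    paste(c(A = "U", C = "G", G = "C", U = "A")[chars], collapse = "")
}
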