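simNb <- function(nF, nS, mean = 100, phi = 0.1, seed = 1) {
    set.seed(seed)
    matrix(rnbinom(nF * nS, mu = mean, size = 1 / phi), nF, nS,
           dimnames = list(sprintf("f%05d", seq_len(nF)),
                           sprintf("s%d", seq_len(nS))))
}

test_that("median-of-ratios size factors behave and match DESeq2", {
    m <- simNb(200, 6, seed = 3)
    expect_equal(sizeFactorsMedianOfRatios(cbind(m[, 1], m[, 1], m[, 1])),
                 rep(1, 3))
    # scale equivariance: doubling one column doubles its factor relative
    # to the other libraries
    m2 <- m; m2[, 2] <- m2[, 2] * 2L
    sf <- sizeFactorsMedianOfRatios(m2)
    sfBase <- sizeFactorsMedianOfRatios(m)
    expect_equal((sf[2] / sf[1]) / (sfBase[2] / sfBase[1]), 2,
                 tolerance = 1e-9)
    # independent implementation cross-check
    expect_equal(sizeFactorsMedianOfRatios(m),
                 unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                 tolerance = 1e-9)
    # fallback when no feature is positive everywhere
    holes <- m[1:10, ]
    holes[cbind(1:10, rep(1:6, length.out = 10))] <- 0L
    expect_warning(sizeFactorsMedianOfRatios(holes), "library-size")
})

test_that("TMM factors are centered, unity on identical columns, and hand-checkable", {
    m <- simNb(300, 4, seed = 5)
    f <- tmmFactors(m)
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
    same <- cbind(m[, 1], m[, 1], m[, 1])
    expect_equal(tmmFactors(same), rep(1, 3))
    # two-sample toy: one wild 4x feature must be trimmed away, so the
    # factor comes from the remaining (equal) features only -> 1
    toy <- cbind(s1 = c(100L, rep(50L, 40)), s2 = c(400L, rep(50L, 40)))
    f2 <- tmmFactors(toy, refColumn = 1L)
    # hand computation: after library-size scaling all M-values except the
    # planted one are equal; the trim removes the outlier; mean M is the
    # common value, and re-centering makes the geometric mean 1
    p1 <- toy[, 1] / sum(toy[, 1]); p2 <- toy[, 2] / sum(toy[, 2])
    M <- log2(p2 / p1); A <- 0.5 * log2(p1 * p2)
    keep <- M >= quantile(M, .3) & M <= quantile(M, .7) &
            A >= quantile(A, .05) & A <= quantile(A, .95)
    hand <- 2^mean(M[keep])
    hand <- c(1, hand) / exp(mean(log(c(1, hand))))
    expect_equal(f2, hand, tolerance = 1e-12)
    allzero <- m; allzero[, 3] <- 0L
    expect_error(tmmFactors(allzero), "s3")
})

test_that("dispersion estimators recover the simulated truth", {
    grp <- factor(rep(c("a", "b"), each = 6))
    pois <- simNb(10000, 12, mean = 100, phi = 1e-9, seed = 7)
    phiHat <- estimateDispersion(pois, grp, method = "moments_pooled")
    expect_lt(median(phiHat), 0.01)
    nb <- simNb(10000, 12, mean = 100, phi = 0.2, seed = 8)
    phiNb <- estimateDispersion(nb, grp, method = "moments_pooled")
    expect_gt(median(phiNb), 0.15)
    expect_lt(median(phiNb), 0.25)
    const <- matrix(50L, 20, 12)
    expect_true(all(estimateDispersion(const, grp,
                                       method = "moments_pooled") == 0))
    expect_error(estimateDispersion(pois[, c(1, 7)],
                                    factor(c("a", "b"))), "single replicate")
})

test_that("Wald test is calibrated on identical groups and powered on planted effects", {
    m <- simNb(2000, 6, mean = 200, phi = 0.05, seed = 9)
    sf <- rep(1, 6)
    nullRes <- nbWaldTest(m, 1:3, 4:6, sf, phi = 0.05)
    expect_lt(abs(median(nullRes$p) - 0.5), 0.1)
    expect_lt(abs(mean(nullRes$log2fc)), 0.05)
    # all-zero feature
    z <- rbind(m, zero = rep(0L, 6))
    zr <- nbWaldTest(z, 1:3, 4:6, sf, 0.05)
    expect_identical(zr["zero", "log2fc"], 0)
    expect_identical(zr["zero", "p"], 1)
    # planted log2fc = +2 at mean 200, phi 0.05: p < 0.05 in >= 90%
    set.seed(10)
    up <- cbind(matrix(rnbinom(600, mu = 200, size = 20), 200, 3),
                matrix(rnbinom(600, mu = 800, size = 20), 200, 3))
    upRes <- nbWaldTest(up, 1:3, 4:6, rep(1, 6), 0.05)
    expect_gte(mean(upRes$p < 0.05), 0.90)
    expect_true(all(upRes$log2fc[upRes$p < 0.05] > 0))
})

test_that("exact test reduces to the binomial split at phi 0 and is symmetric", {
    # symmetric counts: p = 1
    m <- matrix(c(5L, 5L, 5L, 5L), 1)
    expect_equal(nbExactTest(m, 1:2, 3:4, rep(100, 4), phi = 0), 1)
    # phi = 0: agreement with the exact binomial split test on a toy
    sA <- 2L; sB <- 8L; n <- 10L
    m2 <- matrix(c(sA, 0L, sB, 0L), 1)
    got <- nbExactTest(m2, 1:2, 3:4, rep(1e6, 4), phi = 0)
    pr <- dbinom(0:n, n, 0.5)
    want <- sum(pr[pr <= pr[sA + 1] * (1 + 1e-10)])
    expect_equal(got, want, tolerance = 1e-9)
    # p decreases monotonically in the planted fold change
    set.seed(12)
    ps <- vapply(c(0, 1, 2, 3), function(lfc) {
        mm <- cbind(matrix(50L, 5, 3),
                    matrix(as.integer(round(50 * 2^lfc)), 5, 3))
        mean(nbExactTest(mm, 1:3, 4:6, rep(1, 6) * 300, phi = 0.05))
    }, numeric(1))
    expect_true(all(diff(ps) < 0))
})

test_that("BH adjustment matches a brute-force implementation", {
    set.seed(13)
    p <- runif(500)^2
    expect_equal(p.adjust(p, "BH"), oracleBH(p), tolerance = 1e-12)
})

test_that("the consensus rule gates on fold change and both p-values", {
    rec <- data.frame(log2fc = c(2, 0.9, 2, -2, -0.5, 2),
                      padj_a = c(0.01, 0.001, 0.06, 0.01, 0.01, 0.01),
                      p_b = c(0.01, 0.001, 0.01, 0.04, 0.01, 0.06))
    out <- consensusCall(rec)
    expect_identical(out$call, c("up", "ns", "ns", "down", "ns", "ns"))
    expect_error(consensusCall(data.frame(log2fc = 1)), "columns")
    expect_error(consensusCall(data.frame(log2fc = 1, padj_a = NA, p_b = 0.1)),
                 "missing")
})

test_that("multiplying one library by a constant scales its factor, not the calls", {
    m <- simNb(500, 6, mean = 150, phi = 0.05, seed = 14)
    sheet <- data.frame(sample_id = colnames(m),
                        bacterium = rep(c("OP50", "PAO1"), each = 3),
                        generation = "F1", replicate = rep(1:3, 2))
    base <- runDeContrast(m, sheet, "PAO1", "F1")
    m2 <- m; m2[, 4] <- m2[, 4] * 3L
    sf2 <- sizeFactorsMedianOfRatios(m2)
    sf1 <- sizeFactorsMedianOfRatios(m)
    expect_equal((sf2[4] / sf2[1]) / (sf1[4] / sf1[1]), 3, tolerance = 0.01)
    scaled <- runDeContrast(m2, sheet, "PAO1", "F1")
    expect_gt(mean(base$call == scaled$call), 0.98)
})
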