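test_that("seed finder caps at maxSeed and handles no-complement input", {
    set.seed(21)
    m <- randomRna(22)
    hit <- longestComplementSeed(m, revCompRna(m))
    expect_identical(hit$seed_length, 20L)  # 22-nt perfect match, capped
    cfg <- ScanConfig(maxSeed = 22L)
    expect_identical(longestComplementSeed(m, revCompRna(m), cfg)$seed_length,
                     22L)
    # all-A miRNA vs all-C target: no base can pair
    none <- longestComplementSeed(strrep("A", 10), strrep("C", 12))
    expect_identical(none$seed_length, 0L)
    expect_error(longestComplementSeed("ACGUACG", "ACGUACGU"), "at least 8")
    expect_error(longestComplementSeed("ACGUACGX", "ACGUACGU"), "alphabet")
    expect_warning(longestComplementSeed("ACGTACGT", "ACGUACGU"), "T converted")
})

test_that("seed finder equals the exhaustive all-substring oracle", {
    set.seed(22)
    for (i in 1:120) {
        m <- randomRna(sample(15:25, 1))
        t <- randomRna(sample(20:60, 1))
        got <- longestComplementSeed(m, t)
        want <- oracleSeed(m, t)
        expect_identical(got$seed_length, as.integer(want$seed_length),
                         label = sprintf("case %d length", i))
        if (want$seed_length > 0) {
            expect_identical(IRanges::start(got$target_span),
                             as.integer(want$target_start),
                             label = sprintf("case %d target start", i))
            expect_identical(IRanges::start(got$mirna_span),
                             as.integer(want$mirna_start),
                             label = sprintf("case %d mirna start", i))
        }
    }
})

test_that("GU wobble pairs extend seeds only when allowed", {
    # all-G miRNA vs all-U target pairs only as G.U wobble
    m <- strrep("G", 10)
    t <- strrep("U", 12)
    strict <- longestComplementSeed(m, t)
    loose <- longestComplementSeed(m, t, ScanConfig(allowGU = TRUE))
    expect_identical(strict$seed_length, 0L)
    expect_identical(loose$seed_length, 10L)
    expect_true(loose$has_gu)
})

test_that("reverse-complement symmetry preserves the seed length", {
    set.seed(23)
    for (i in 1:40) {
        m <- randomRna(18); t <- randomRna(40)
        a <- longestComplementSeed(m, t)$seed_length
        b <- longestComplementSeed(revCompRna(t), revCompRna(m))$seed_length
        expect_identical(a, b)
    }
})

test_that("duplex energies equal hand-summed table terms", {
    tab <- nnParameters()
    tK <- 20 + 273.15
    gAt <- function(top, bottom, temp = tK) {
        i <- which(tab$top == top & tab$bottom == bottom)
        tab$dH[i] - temp * tab$dS[i] / 1000
    }
    init <- attr(tab, "initiation")
    initG <- init[["dH"]] - tK * init[["dS"]] / 1000
    au <- attr(tab, "terminal_AU")
    auG <- au[["dH"]] - tK * au[["dS"]] / 1000
    # 5'GC3' / 5'GC3': single GC/CG stack, no AU ends
    expect_equal(duplexEnergy("GC", "GC"), initG + gAt("GC", "CG"),
                 tolerance = 1e-9)
    # 5'GGG3' / 5'CCC3': two GG/CC stacks
    expect_equal(duplexEnergy("GGG", "CCC"), initG + 2 * gAt("GG", "CC"),
                 tolerance = 1e-9)
    # 5'AU3' / 5'AU3': one AU/UA stack + two terminal AU penalties
    expect_equal(duplexEnergy("AU", "AU"), initG + gAt("AU", "UA") + 2 * auG,
                 tolerance = 1e-9)
    # 5'GAC3' / 5'GUC3': GA/CU stack + AC/UG stack (== GU/CA read from
    # the other strand)
    expect_equal(duplexEnergy("GAC", "GUC"),
                 initG + gAt("GA", "CU") + gAt("GU", "CA"),
                 tolerance = 1e-9)
    # 5'ACGU3' / 5'ACGU3': AC/UG (== GU/CA), CG/GC, GU/CA + two AU ends
    expect_equal(duplexEnergy("ACGU", "ACGU"),
                 initG + 2 * gAt("GU", "CA") + gAt("CG", "GC") + 2 * auG,
                 tolerance = 1e-9)
    expect_error(duplexEnergy("GG", "GG"), "paired")
    expect_error(duplexEnergy("G", "C"), "two consecutive")
})

test_that("helices are more stable cold and grow monotonically with good stacks", {
    set.seed(24)
    for (i in 1:25) {
        w <- randomRna(sample(4:12, 1))
        comp <- revCompRna(w)
        g20 <- duplexEnergy(w, comp, temperature = 20)
        g37 <- duplexEnergy(w, comp, temperature = 37)
        expect_lte(g20, g37)
    }
    # appending a pair whose stack term is negative never raises deltaG
    # (GC extension of a GC-ended helix adds a pure stack, no end penalty)
    base <- "GCGC"; ext <- "GCGCG"
    dg1 <- duplexEnergy(base, revCompRna(base))
    dg2 <- duplexEnergy(ext, revCompRna(ext))
    expect_lt(dg2, dg1)
})

test_that("target screen ranks the planted complement first and filters monotonically", {
    set.seed(25)
    mirna <- c(mir = randomRna(22))
    planted <- paste0(randomRna(15),
                      revCompRna(substr(mirna, 4, 17)),  # 14-nt perfect site
                      randomRna(15))
    decoys <- setNames(vapply(1:20, function(i) randomRna(44), ""),
                       sprintf("decoy%02d", 1:20))
    cands <- c(planted = planted, decoys)
    hits <- screenTargets(mirna, cands)
    expect_gt(nrow(hits), 0L)
    expect_identical(hits$target_id[1], "planted")
    expect_gte(hits$seed_length[1], 14L)
    expect_lt(hits$nfe[1], 0)
    # raising minSeed never adds hits
    n12 <- nrow(screenTargets(mirna, cands, ScanConfig(minSeed = 12)))
    n14 <- nrow(screenTargets(mirna, cands, ScanConfig(minSeed = 14)))
    n19 <- nrow(screenTargets(mirna, cands,
                              ScanConfig(minSeed = 19, maxSeed = 20)))
    expect_true(n12 >= n14 && n14 >= n19)
    # min_seed above every hit: empty
    expect_identical(nrow(screenTargets(mirna, decoys,
                                        ScanConfig(minSeed = 20))), 0L)
    # duplicated candidate sequence: identical hits, deterministic id order
    dup <- c(a = planted, b = planted)
    hd <- screenTargets(mirna, dup)
    expect_identical(hd$target_id, c("a", "b"))
    expect_identical(hd$seed_length[1], hd$seed_length[2])
    expect_identical(hd$nfe[1], hd$nfe[2])
    expect_warning(out <- screenTargets(mirna, character(0)), "empty")
    expect_identical(nrow(out), 0L)
})

test_that("scan configuration enforces its seed ordering", {
    expect_error(ScanConfig(minSeed = 6), "defaultSeed")
    expect_error(ScanConfig(minSeed = 25, maxSeed = 20), "minSeed")
    cfg <- ScanConfig()
    expect_identical(cfg@minSeed, 12L)
    expect_identical(cfg@maxSeed, 20L)
    expect_identical(cfg@defaultSeed, 8L)
    expect_identical(cfg@temperature, 20)
})
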