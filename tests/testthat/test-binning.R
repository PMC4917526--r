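# Differential-coverage seeding, TNF refinement, link recovery,
# filtering and bin statistics.

test_that("two coverage-contrasted genomes seed into two clean clusters", {
    com <- simulateCommunity(twoGenomeSpec(), seed = 71)
    cov <- normalizedCovOf(com)
    lab <- seedBins(cov, scaffoldLengthsOf(com))
    tv <- truthVector(com)
    expect_equal(length(unique(stats::na.omit(lab))), 2L)
    tab <- table(lab, tv[names(lab)])
    # zero cross-assignments: each cluster holds one genome only
    expect_true(all(apply(tab, 1, function(r) sum(r > 0)) == 1))
})

test_that("a single dominant population forms a single cluster", {
    spec <- CommunitySpec(data.frame(
        name = c("solo", "ghost"), length = c(2e5, 2e5),
        gc = c(0.5, 0.5), markovOrder = 1L,
        cov_TW = c(80, 0), cov_AW = c(40, 0),
        nMarkers = 0L, nDuplicated = 0L,
        fragMean = 4000, fragSigma = 0.5))
    com <- simulateCommunity(spec, seed = 72)
    cov <- normalizedCovOf(com)
    lab <- seedBins(cov, scaffoldLengthsOf(com))
    tv <- truthVector(com)
    solo <- lab[names(tv)[tv == "solo"]]
    expect_equal(length(unique(solo)), 1L)
    expect_false(anyNA(solo))
})

test_that("all-zero coverage yields no bins with a warning", {
    raw <- matrix(0, 6, 2, dimnames = list(sprintf("s%d", 1:6),
                                           c("x", "y")))
    cm <- normalizeCoverage(CoverageMatrix(raw, c(x = 1, y = 1)))
    expect_warning(lab <- seedBins(cm, stats::setNames(rep(1000, 6),
                                                       rownames(raw))),
                   "all-zero")
    expect_true(all(is.na(lab)))
})

test_that("refinement splits coverage-confounded genomes of distinct GC", {
    spec <- twoGenomeSpec(covA = c(50, 50), covB = c(50, 50),
                          gc = c(0.30, 0.64))
    com <- simulateCommunity(spec, seed = 73)
    cov <- normalizedCovOf(com)
    lab <- seedBins(cov, scaffoldLengthsOf(com))
    expect_equal(length(unique(stats::na.omit(lab))), 1L)
    ref <- refineBins(lab, tnfMatrix(scaffolds(com)))
    tv <- truthVector(com)
    tab <- table(ref, tv[names(ref)])
    expect_equal(nrow(tab), 2L)
    expect_true(all(apply(tab, 1, function(r) sum(r > 0)) == 1))
})

test_that("refinement never moves scaffolds across seeded clusters", {
    com <- simulateCommunity(twoGenomeSpec(gc = c(0.35, 0.60)),
                             seed = 74)
    cov <- normalizedCovOf(com)
    lab <- seedBins(cov, scaffoldLengthsOf(com))
    ref <- refineBins(lab, tnfMatrix(scaffolds(com)))
    keep <- !is.na(lab)
    expect_equal(sub("\\.\\d+$", "", ref[keep]), lab[keep])
    expect_equal(is.na(ref), is.na(lab))
})

test_that("a unimodal cluster passes refinement unchanged", {
    spec <- CommunitySpec(data.frame(
        name = c("one", "two"), length = 2e5, gc = c(0.50, 0.50),
        markovOrder = 1L, cov_TW = c(100, 1), cov_AW = c(1, 100),
        nMarkers = 0L, nDuplicated = 0L, fragMean = 4000,
        fragSigma = 0.5))
    com <- simulateCommunity(spec, seed = 75)
    cov <- normalizedCovOf(com)
    lab <- seedBins(cov, scaffoldLengthsOf(com))
    # each genome is its own unimodal coverage cluster: no split labels
    ref <- refineBins(lab, tnfMatrix(scaffolds(com)))
    expect_true(all(!grepl("\\.", stats::na.omit(ref))))
})

test_that("link recovery follows the weight and tie rules", {
    labels <- c(s1 = "bin1", s2 = "bin1", s3 = "bin2", s4 = NA, s5 = NA,
                s6 = NA)
    links <- data.frame(a = c("s4", "s4", "s5", "s5", "s6"),
                        b = c("s1", "s2", "s1", "s3", "s3"),
                        weight = c(3, 2, 2, 2, 2))
    out <- recoverLinked(labels, links, minWeight = 3)
    expect_equal(unname(out["s4"]), "bin1")    # 5 links to bin1
    expect_true(is.na(out["s5"]))              # tie 2 vs 2
    expect_true(is.na(out["s6"]))              # 2 < minWeight
    # assigned labels never change
    expect_equal(out[c("s1", "s2", "s3")], labels[c("s1", "s2", "s3")])
})

test_that("short scaffolds dropped from seeding are recovered by links", {
    spec <- twoGenomeSpec(fragMean = 4000, fragSigma = 0.7)
    com <- simulateCommunity(spec, seed = 76)
    cov <- normalizedCovOf(com)
    lens <- scaffoldLengthsOf(com)
    lab <- seedBins(cov, lens, minLen = 1500)
    dropped <- names(lab)[is.na(lab) & lens < 1500]
    expect_gt(length(dropped), 5)
    out <- recoverLinked(lab, linkGraph(com), minWeight = 3)
    tv <- truthVector(com)
    rec <- dropped[!is.na(out[dropped])]
    correct <- vapply(rec, function(s) {
        peers <- names(out)[!is.na(out) & out == out[s]]
        maj <- names(sort(table(tv[peers]), decreasing = TRUE))[1]
        maj == tv[s]
    }, logical(1))
    expect_gte(length(rec) / length(dropped), 0.9)
    expect_gte(mean(correct), 0.9)
})

test_that("bin statistics compute length-weighted GC and coverage", {
    sc <- Biostrings::DNAStringSet(c(
        g1 = paste(rep("GGCC", 250), collapse = ""),
        a1 = paste(rep(c("A", "G"), c(600, 400)), collapse = ""),
        a2 = paste(rep(c("A", "G"), c(1200, 1800)), collapse = "")))
    raw <- matrix(c(10, 4, 6, 1, 2, 3), ncol = 2,
                  dimnames = list(names(sc), c("x", "y")))
    cm <- normalizeCoverage(CoverageMatrix(raw, c(x = 5, y = 5)))
    st <- binStats(c(g1 = "solo", a1 = "pair", a2 = "pair"), sc, cm)
    expect_equal(st$gcPercent[st$bin == "solo"], 100)
    expect_equal(st$gcPercent[st$bin == "pair"], 55)  # 40% and 60% by length
    expect_equal(st$totalLength, c(4000, 1000))
    expect_equal(st$cov_x[st$bin == "pair"],
                 (4 * 1000 + 6 * 3000) / 4000)
})

test_that("bin statistics agree with brute-force recomputation", {
    com <- simulateCommunity(twoGenomeSpec(), seed = 77)
    cov <- normalizedCovOf(com)
    tv <- truthVector(com)
    st <- binStats(tv, scaffolds(com), cov)
    sc <- scaffolds(com)
    m <- normalizedCoverage(cov)
    for (g in unique(tv)) {
        ids <- names(tv)[tv == g]
        w <- Biostrings::width(sc[ids])
        gc <- sum(Biostrings::letterFrequency(sc[ids], "GC")[, 1])
        row <- st[st$bin == g, ]
        expect_equal(row$nScaffolds, length(ids))
        expect_equal(row$totalLength, sum(w))
        expect_equal(row$gcPercent, 100 * gc / sum(w))
        expect_equal(row$cov_TW, sum(m[ids, "TW"] * w) / sum(w))
    }
})

test_that("filtering rejects only bins both incomplete and small", {
    stats <- data.frame(bin = c("big", "small", "full"),
                        nScaffolds = c(224, 10, 50),
                        totalLength = c(4145951, 3e5, 2e5),
                        gcPercent = 50,
                        cov_TW = 1, cov_AW = 1)
    census <- data.frame(bin = c("big", "small", "full"),
                         uniqueMarkers = c(14L, 16L, 105L),
                         totalHits = c(14L, 16L, 105L),
                         duplicatedMarkers = 0L, refSize = 105L)
    out <- filterBins(stats, census, minCompleteness = 20,
                      minSize = 1e6)
    # 13% complete but 4.1 Mb: kept; 15% and 0.3 Mb: rejected;
    # 100% complete: kept regardless of size
    expect_setequal(out$kept$bin, c("big", "full"))
    expect_equal(out$rejected$bin, "small")
    expect_match(out$rejected$reason, "completeness")
})

test_that("binning labels are stable under input permutation", {
    com <- simulateCommunity(twoGenomeSpec(), seed = 78)
    cov <- normalizedCovOf(com)
    lens <- scaffoldLengthsOf(com)
    lab <- seedBins(cov, lens)
    set.seed(79)
    perm <- sample(rownames(rawCoverage(cov)))
    covP <- normalizeCoverage(CoverageMatrix(
        rawCoverage(cov)[perm, ], alignedReads(cov)))
    labP <- seedBins(covP, lens)
    expect_equal(labP[names(lab)], lab)
})
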