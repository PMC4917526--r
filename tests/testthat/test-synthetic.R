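# Synthetic community generator: sequence model, fragmentation, depth
# and determinism contracts.

test_that("generated genomes hit their GC target", {
    set.seed(51)
    for (gc in c(0.30, 0.50, 0.64)) {
        g <- generateGenome(1e5, gc)
        got <- Biostrings::letterFrequency(g, "GC", as.prob = TRUE)[1]
        expect_lt(abs(got - gc), 0.02)
    }
    # uniform transition matrix at gc 0.5
    set.seed(52)
    g <- generateGenome(1e5, 0.5,
                        transition = matrix(0.25, 4, 4))
    got <- Biostrings::letterFrequency(g, "GC", as.prob = TRUE)[1]
    expect_gte(got, 0.48); expect_lte(got, 0.52)
    expect_error(generateGenome(0, 0.5), "positive")
    expect_error(generateGenome(10, 1.2), "gc")
    expect_error(generateGenome(10, 0.5, markovOrder = 0), "markovOrder")
})

test_that("same seed reproduces the same genome", {
    set.seed(53); a <- generateGenome(5000, 0.45)
    set.seed(53); b <- generateGenome(5000, 0.45)
    expect_equal(as.character(a), as.character(b))
})

test_that("distinct GC families are separable by brute-force TNF distance", {
    set.seed(54)
    lowG <- generateGenome(6000, 0.30)
    set.seed(55)
    highG <- generateGenome(6000, 0.64)
    lows <- lapply(seq(1, 4001, 2000), function(i)
        as.character(Biostrings::subseq(lowG, i, i + 1999)))
    highs <- lapply(seq(1, 4001, 2000), function(i)
        as.character(Biostrings::subseq(highG, i, i + 1999)))
    vl <- lapply(lows, bruteTnf)
    vh <- lapply(highs, bruteTnf)
    d <- function(a, b) sqrt(sum((a - b)^2))
    within <- c(d(vl[[1]], vl[[2]]), d(vl[[2]], vl[[3]]),
                d(vh[[1]], vh[[2]]), d(vh[[2]], vh[[3]]))
    between <- c(d(vl[[1]], vh[[1]]), d(vl[[2]], vh[[2]]),
                 d(vl[[3]], vh[[3]]))
    expect_gt(mean(between), mean(within))
})

test_that("fragmentation honours min length and partitions a prefix", {
    set.seed(56)
    g <- generateGenome(10000, 0.5)
    sc <- fragmentGenome(g, fragMean = 2000, minLen = 500)
    w <- Biostrings::width(sc)
    expect_true(all(w >= 500))
    expect_lte(sum(w), 10000)
    # direct summation audit against the source prefix
    expect_equal(paste(as.character(sc), collapse = ""),
                 as.character(Biostrings::subseq(g, 1, sum(w))))
    # degenerate: genome length == mean -> exactly one scaffold
    sc1 <- fragmentGenome(generateGenome(1000, 0.5), fragMean = 1000)
    expect_equal(length(sc1), 1L)
    expect_gte(Biostrings::width(sc1), 500L)
    expect_lte(Biostrings::width(sc1), 1000L)
    expect_error(fragmentGenome(g, fragMean = 300, minLen = 500),
                 "minLen")
})

test_that("depth simulation honours the noise model", {
    set.seed(57)
    sc <- fragmentGenome(generateGenome(12000, 0.5), fragMean = 6000)
    zero <- simulateDepth(sc, 0)
    expect_true(all(zero$depth == 0))
    flat <- simulateDepth(sc, 10, noise = "none")
    expect_true(all(flat$depth == 10))
    set.seed(58)
    pois <- simulateDepth(sc, 100, noise = "poisson")
    n <- nrow(pois)
    se <- sqrt(100 / n)
    expect_lt(abs(mean(pois$depth) - 100), 3 * se)
    expect_true(all(pois$depth >= 0))
    expect_error(simulateDepth(sc, 10, noise = "gamma"), "arg")
})

test_that("marker planting rejects over-large requests", {
    set.seed(59)
    sc <- fragmentGenome(generateGenome(20000, 0.5), fragMean = 2000)
    expect_error(plantMarkers(sc, 106), "exceeds")
    expect_equal(nrow(plantMarkers(sc, 0)), 0L)
    h <- plantMarkers(sc, 30, 4)
    expect_equal(length(unique(h$marker)), 30L)
    expect_equal(nrow(h), 34L)
    expect_true(all(h$start < h$end))
})

test_that("the community is byte-deterministic and conserves scaffolds", {
    spec <- twoGenomeSpec()
    c1 <- simulateCommunity(spec, seed = 60)
    c2 <- simulateCommunity(spec, seed = 60)
    expect_identical(as.character(scaffolds(c1)),
                     as.character(scaffolds(c2)))
    expect_identical(depthTables(c1), depthTables(c2))
    expect_identical(markerHits(c1), markerHits(c2))
    expect_identical(truthTable(c1), truthTable(c2))
    # written outputs byte-identical too
    d1 <- file.path(tempdir(), "com1"); d2 <- file.path(tempdir(), "com2")
    writeCommunity(c1, d1); writeCommunity(c2, d2)
    for (f in list.files(d1))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    # conservation: every scaffold in exactly one truth entry
    expect_setequal(truthTable(c1)$scaffold, names(scaffolds(c1)))
    expect_false(anyDuplicated(truthTable(c1)$scaffold) > 0)
    # different seed changes the output
    c3 <- simulateCommunity(spec, seed = 61)
    expect_false(identical(as.character(scaffolds(c1)),
                           as.character(scaffolds(c3))))
})

test_that("invalid community specs are rejected", {
    g <- twoGenomeSpec()@genomes
    bad <- g; bad$gc[1] <- 1.5
    expect_error(CommunitySpec(bad), "gc")
    bad <- g; bad$length[1] <- 5 * bad$fragMean[1]
    expect_error(CommunitySpec(bad), "10")
    bad <- g; bad$nDuplicated[1] <- bad$nMarkers[1] + 1
    expect_error(CommunitySpec(bad), "nDuplicated")
    expect_error(CommunitySpec(g[1, , drop = FALSE]), "2 genomes")
    expect_error(CommunitySpec(g, samples = c("a", "a")), "distinct")
})

test_that("the default 13-genome community mirrors the study design", {
    spec <- witheringCommunitySpec()
    g <- spec@genomes
    expect_equal(nrow(g), 13L)
    expect_equal(range(g$gc), c(0.291, 0.639))
    expect_equal(g$nMarkers,
                 c(105, 105, 72, 80, 40, 89, 66, 68, 14, 68, 104, 80, 75))
    ratios <- pmax(g$cov_TW, g$cov_AW) / pmin(g$cov_TW, g$cov_AW)
    expect_true(all(ratios >= 20))
    expect_lte(max(ratios), 4100)
})
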