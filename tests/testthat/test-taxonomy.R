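# Identity-threshold rank assignment and consensus taxonomy.

test_that("mean identity averages genes with hits and counts no-hits", {
    ev <- data.frame(bin = "b1", gene = c("g1", "g2", "g3"),
                     ntIdentity = c(98, 98, 98.3),
                     aaIdentity = c(99, NA, 97))
    m <- meanIdentity(ev)
    expect_equal(m$meanNtIdentity, mean(c(98, 98, 98.3)))
    expect_equal(m$meanAaIdentity, 98)
    expect_equal(m$nNoAaHit, 1L)
    one <- meanIdentity(data.frame(bin = "b", gene = "g",
                                   ntIdentity = 90.05,
                                   aaIdentity = NA))
    expect_equal(one$meanNtIdentity, 90.05)
    expect_error(meanIdentity(ev[0, ]), "no identity evidence")
    bad <- ev; bad$ntIdentity[1] <- 105
    expect_error(meanIdentity(bad), "0, 100")
})

test_that("mean identity equals a brute-force accumulation", {
    set.seed(81)
    ev <- data.frame(bin = sample(c("x", "y"), 60, TRUE),
                     gene = sprintf("g%02d", 1:60),
                     ntIdentity = ifelse(runif(60) < 0.2, NA,
                                         runif(60, 60, 100)),
                     aaIdentity = runif(60, 60, 100))
    m <- meanIdentity(ev)
    for (b in c("x", "y")) {
        sub <- ev[ev$bin == b, ]
        acc <- 0; n <- 0
        for (i in seq_len(nrow(sub)))
            if (!is.na(sub$ntIdentity[i])) {
                acc <- acc + sub$ntIdentity[i]; n <- n + 1
            }
        expect_equal(m$meanNtIdentity[m$bin == b], acc / n)
    }
})

test_that("rank thresholds are inclusive with a no-call below phylum", {
    expect_equal(assignRank(98.1), "species")
    expect_equal(assignRank(87.8), "genus")
    expect_equal(assignRank(75.0), "phylum")
    expect_true(is.na(assignRank(74.999)))
    expect_equal(assignRank(95), "species")
    expect_equal(assignRank(85), "genus")
    expect_error(assignRank(101), "identity")
    # monotone: deeper identity never gives a shallower rank
    depth <- function(r) match(r, c("phylum", "genus", "species"))
    ids <- seq(75, 100, by = 0.5)
    expect_true(all(diff(depth(assignRank(ids))) >= 0))
})

test_that("the nine high-identity study bins map to their printed depth", {
    blastn <- c(bin4 = 98.1, bin5 = 97.2, bin8 = 97.1,
                bin2 = 86.5, bin6 = 87.8, bin7 = 88.1, bin9 = 90.05,
                bin10 = 86.5, bin13 = 89.1)
    want <- c(rep("species", 3), rep("genus", 6))
    expect_equal(unname(assignRank(blastn)), want)
})

test_that("consensus prefers nucleotide at genus or better", {
    res <- consensusTaxonomy(
        "bin5", ntIdentity = 97.2,
        ntLineage = "k__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Enterobacteriales;f__Enterobacteriaceae;g__Pantoea;s__Pantoea vagans",
        aaIdentity = 99.2,
        aaLineage = "k__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Enterobacteriales;f__Enterobacteriaceae;g__Pantoea")
    expect_equal(res$rank, "species")
    expect_equal(res$method, "nucleotide")
    expect_match(res$lineage, "s__Pantoea vagans")
})

test_that("low nucleotide identity falls back to protein/placement consensus", {
    clostr <- "k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Clostridiaceae;g__Clostridium"
    res <- consensusTaxonomy("bin1", ntIdentity = 66.4,
                             ntLineage = clostr,
                             aaIdentity = 81.5, aaLineage = clostr,
                             placementLineage = clostr,
                             placementConfidence = "high")
    expect_equal(res$rank, "genus")
    expect_equal(res$method, "consensus")
    expect_match(res$lineage, "g__Clostridium")
})

test_that("disagreeing fallback lineages resolve to the common ancestor", {
    a <- "k__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Enterobacteriales;f__Enterobacteriaceae;g__Pantoea"
    b <- "k__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Enterobacteriales;f__Enterobacteriaceae;g__Erwinia"
    res <- consensusTaxonomy("binX", ntIdentity = 60, ntLineage = a,
                             aaIdentity = 70, aaLineage = a,
                             placementLineage = b,
                             placementConfidence = "medium")
    expect_equal(res$rank, "family")
    expect_match(res$lineage, "f__Enterobacteriaceae$")
    # low-confidence placement is ignored: protein lineage used directly
    res2 <- consensusTaxonomy("binX", ntIdentity = 60, ntLineage = a,
                              aaIdentity = 70, aaLineage = a,
                              placementLineage = b,
                              placementConfidence = "low")
    expect_equal(res2$method, "protein")
    expect_equal(res2$rank, "genus")
    expect_error(consensusTaxonomy("binY"), "no taxonomic evidence")
})

test_that("assignTaxonomy drives consensus across an evidence table", {
    ev <- rbind(
        data.frame(bin = "b1", gene = sprintf("g%d", 1:3),
                   ntIdentity = c(97, 98, 96.6),
                   ntLineage = "k__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Enterobacteriales;f__Enterobacteriaceae;g__Erwinia;s__Erwinia billingiae",
                   aaIdentity = 99,
                   aaLineage = "k__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Enterobacteriales;f__Enterobacteriaceae;g__Erwinia"),
        data.frame(bin = "b2", gene = sprintf("g%d", 1:2),
                   ntIdentity = c(60, 64),
                   ntLineage = "k__Bacteria;p__Firmicutes",
                   aaIdentity = 80,
                   aaLineage = "k__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales"))
    pl <- data.frame(bin = "b2",
                     lineage = "k__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales",
                     confidence = "medium")
    res <- assignTaxonomy(ev, pl)
    expect_equal(res$rank[res$bin == "b1"], "species")
    expect_equal(res$rank[res$bin == "b2"], "order")
    expect_equal(res$method[res$bin == "b2"], "consensus")
})

test_that("lineage parsing rejects malformed fields", {
    expect_error(parseLineage("k__Bacteria;xx__Nope"), "malformed")
    p <- parseLineage("k__Bacteria;p__Firmicutes;c__Clostridia")
    expect_equal(unname(p["class"]), "Clostridia")
})
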