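# Fixtures built in code and independent brute-force oracles used
# across the suite.

## small two-genome spec with strong two-sample coverage contrast
twoGenomeSpec <- function(covA = c(100, 5), covB = c(5, 100),
                          gc = c(0.30, 0.64), len = 2e5,
                          nMarkers = c(20, 30), nDup = c(2, 0),
                          fragMean = 4000, fragSigma = 0.5) {
    CommunitySpec(data.frame(
        name = c("genomeA", "genomeB"), length = len, gc = gc,
        markovOrder = 1L, cov_TW = c(covA[1], covB[1]),
        cov_AW = c(covA[2], covB[2]), nMarkers = nMarkers,
        nDuplicated = nDup, fragMean = fragMean, fragSigma = fragSigma))
}

## truth as a named scaffold -> genome vector
truthVector <- function(community) {
    tt <- truthTable(community)
    stats::setNames(tt$genome, tt$scaffold)
}

scaffoldLengthsOf <- function(community) {
    sc <- scaffolds(community)
    stats::setNames(as.numeric(Biostrings::width(sc)), names(sc))
}

normalizedCovOf <- function(community) {
    normalizeCoverage(coverageFromDepth(
        depthTables(community), scaffoldLengthsOf(community),
        alignedReads(community)))
}

## ---- independent oracles ------------------------------------------------

## brute-force canonical TNF by explicit window enumeration
bruteTnf <- function(seq) {
    seq <- toupper(as.character(seq))
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    canon <- canonicalTetramers()
    counts <- stats::setNames(numeric(length(canon)), canon)
    n <- nchar(seq)
    for (i in seq_len(max(0, n - 3))) {
        w <- substr(seq, i, i + 3)
        ch <- strsplit(w, "")[[1]]
        if (!all(ch %in% names(comp))) next
        rc <- paste(rev(unname(comp[ch])), collapse = "")
        key <- min(w, rc)
        counts[key] <- counts[key] + 1
    }
    if (sum(counts) == 0) stop("no valid window")
    counts / sum(counts)
}

## brute-force per-base mean coverage by an explicit accumulation loop
bruteMeanCoverage <- function(depth, scaffoldLengths) {
    out <- stats::setNames(numeric(length(scaffoldLengths)),
                           names(scaffoldLengths))
    for (i in seq_len(nrow(depth))) {
        s <- depth$scaffold[i]
        out[s] <- out[s] + depth$depth[i]
    }
    out / scaffoldLengths
}

## gene-by-gene accumulation oracle for functional abundance
bruteFunctionalAbundance <- function(genes, covVec) {
    acc <- list()
    for (i in seq_len(nrow(genes))) {
        for (lab in strsplit(as.character(genes$category[i]),
                             "[,;]\\s*")[[1]]) {
            if (is.null(acc[[lab]])) acc[[lab]] <- c(0, 0)
            acc[[lab]] <- acc[[lab]] + c(1, covVec[[genes$scaffold[i]]])
        }
    }
    acc
}
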