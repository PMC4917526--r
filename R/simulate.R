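# Synthetic two-sample metagenome community generator.
#
# Each genome is an order-k Markov chain (default order 1) whose
# transition matrix is drawn once per genome as a Dirichlet perturbation
# around a GC-constrained base matrix, then rescaled so every row's G+C
# mass equals the GC target exactly; the per-genome perturbation gives
# each genome a distinguishable tetranucleotide signature, standing in
# for the compositional differences between real genomes. Scaffold
# lengths are lognormal, truncated at the assembly's minimum scaffold
# length; per-base depth is Poisson around the genome's per-sample mean
# coverage.

#' Build a two-sample community specification
#'
#' @param genomes data.frame of genome parameters (see
#'   \linkS4class{CommunitySpec} for the required columns).
#' @param samples character vector of two sample identifiers.
#' @return a validated \linkS4class{CommunitySpec}.
#' @export
CommunitySpec <- function(genomes, samples = c("TW", "AW")) {
    methods::new("CommunitySpec", genomes = as.data.frame(genomes),
                 samples = samples)
}

## GC-constrained order-k transition matrix with per-genome Dirichlet
## perturbation. Rows are contexts (4^order), columns A,C,G,T; after
## perturbation each row is rescaled so P(G)+P(C) == gc exactly, which
## pins the chain's stationary GC at the target for any order.
.gcTransitionMatrix <- function(gc, order = 1, concentration = 50) {
    base <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    ncontext <- 4^order
    m <- matrix(0, ncontext, 4)
    for (r in seq_len(ncontext)) {
        g <- stats::rgamma(4, shape = concentration * base)
        p <- g / sum(g)
        at <- p[1] + p[4]
        gcm <- p[2] + p[3]
        # degenerate draws: fall back to the base row
        if (at <= 0 || gcm <= 0) p <- base
        else p <- c(p[1] / at * (1 - gc), p[2] / gcm * gc,
                    p[3] / gcm * gc, p[4] / at * (1 - gc))
        m[r, ] <- p
    }
    m
}

#' Generate one genome sequence from a Markov model
#'
#' @param length sequence length in bp (> 0).
#' @param gc target GC fraction in (0, 1).
#' @param markovOrder order of the Markov chain (>= 1).
#' @param transition optional 4^order x 4 row-stochastic matrix; drawn
#'   via a GC-constrained Dirichlet perturbation when NULL.
#' @param concentration Dirichlet concentration of the perturbation
#'   (smaller = more distinctive composition; default 50).
#' @return a \code{DNAString}. Realized GC lands within about 2
#'   percentage points of the target (every transition row carries
#'   exactly the target's GC mass, so only binomial noise remains).
#' @export
generateGenome <- function(length, gc, markovOrder = 1, transition = NULL,
                           concentration = 50) {
    if (length <= 0) stop("genome length must be positive")
    if (gc <= 0 || gc >= 1) stop("gc target must lie in (0, 1)")
    if (markovOrder < 1) stop("markovOrder must be >= 1")
    if (is.null(transition))
        transition <- .gcTransitionMatrix(gc, markovOrder, concentration)
    if (nrow(transition) != 4^markovOrder || ncol(transition) != 4)
        stop("transition matrix must be 4^order x 4")
    init <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    states <- cpp_markov_chain(as.integer(length), init, transition)
    Biostrings::DNAString(
        paste(c("A", "C", "G", "T")[states + 1L], collapse = ""))
}

#' Fragment a genome into scaffolds
#'
#' Scaffold lengths are drawn from a lognormal with the requested mean
#' and log-scale dispersion, truncated below at \code{minLen}; pieces
#' are cut sequentially from the genome start, so the scaffolds
#' partition a prefix of the genome and their total length never
#' exceeds the genome length.
#'
#' @param genome a \code{DNAString} (or character) genome sequence.
#' @param fragMean mean scaffold length in bp (must be >= \code{minLen}).
#' @param fragSigma lognormal sdlog (default 0.5).
#' @param minLen minimum scaffold length (default 500, the usual
#'   assembly cutoff).
#' @param prefix scaffold id prefix (default \code{"scaffold"}); ids are
#'   \code{<prefix>_s<k>} in genome order.
#' @return a named \code{DNAStringSet}.
#' @export
fragmentGenome <- function(genome, fragMean, fragSigma = 0.5, minLen = 500,
                           prefix = "scaffold") {
    if (minLen < 1) stop("minLen must be >= 1")
    if (fragMean < minLen)
        stop("mean scaffold length (", fragMean,
             ") must be >= minLen (", minLen, ")")
    total <- if (methods::is(genome, "DNAString")) length(genome) else
        nchar(genome)
    meanlog <- log(fragMean) - fragSigma^2 / 2
    starts <- integer()
    lens <- integer()
    at <- 1L
    while (total - at + 1L >= minLen) {
        l <- max(minLen, round(stats::rlnorm(1, meanlog, fragSigma)))
        l <- min(l, total - at + 1L)
        if (l < minLen) break
        starts <- c(starts, at)
        lens <- c(lens, as.integer(l))
        at <- at + as.integer(l)
    }
    if (!length(starts))
        stop("genome shorter than minLen; no scaffold can be emitted")
    out <- Biostrings::DNAStringSet(genome, start = starts,
                                    width = lens)
    names(out) <- sprintf("%s_s%04d", prefix, seq_along(starts))
    out
}

#' Simulate per-base depth tables
#'
#' @param scaffolds a named \code{DNAStringSet} (only widths and names
#'   are used).
#' @param abundance mean coverage of these scaffolds in this sample
#'   (>= 0).
#' @param noise \code{"poisson"} (per-base Poisson around the mean) or
#'   \code{"none"} (every base exactly the mean, rounded).
#' @return data.frame with columns \code{scaffold}, \code{pos}
#'   (0-based), \code{depth}.
#' @export
simulateDepth <- function(scaffolds, abundance,
                          noise = c("poisson", "none")) {
    noise <- match.arg(noise)
    if (abundance < 0) stop("abundance must be >= 0")
    w <- Biostrings::width(scaffolds)
    n <- sum(w)
    depth <- if (abundance == 0) integer(n)
        else if (noise == "none") rep(as.integer(round(abundance)), n)
        else stats::rpois(n, abundance)
    data.frame(scaffold = rep(names(scaffolds), w),
               pos = unlist(lapply(w, function(k) seq_len(k) - 1L),
                            use.names = FALSE),
               depth = depth, stringsAsFactors = FALSE)
}

#' Plant essential-gene marker hits on a genome's scaffolds
#'
#' Markers are abstract interval annotations (downstream marker census
#' consumes hit tables, not sequence); each planted marker gets one hit
#' on a length-weighted random scaffold, and \code{nDuplicated} of them
#' get a second hit.
#'
#' @param scaffolds named \code{DNAStringSet} of one genome's scaffolds.
#' @param nPresent number of distinct markers to plant (0..reference
#'   size).
#' @param nDuplicated how many of the planted markers occur twice.
#' @param reference marker id vector (default the 105-gene set).
#' @return data.frame with columns \code{scaffold}, \code{marker},
#'   \code{start}, \code{end}, \code{score}.
#' @export
plantMarkers <- function(scaffolds, nPresent, nDuplicated = 0,
                         reference = markerReference()) {
    if (nPresent > length(reference))
        stop("nPresent (", nPresent, ") exceeds the reference set size (",
             length(reference), ")")
    if (nDuplicated > nPresent)
        stop("nDuplicated cannot exceed nPresent")
    if (nPresent == 0)
        return(data.frame(scaffold = character(), marker = character(),
                          start = integer(), end = integer(),
                          score = numeric(), stringsAsFactors = FALSE))
    ids <- sample(reference, nPresent)
    dup <- if (nDuplicated > 0) sample(ids, nDuplicated) else character()
    markers <- c(ids, dup)
    w <- Biostrings::width(scaffolds)
    host <- sample(seq_along(scaffolds), length(markers), replace = TRUE,
                   prob = w)
    len <- pmax(2L, pmin(900L, w[host] - 1L))
    start <- vapply(seq_along(host), function(i)
        sample.int(w[host[i]] - len[i] + 1L, 1L) - 1L, integer(1))
    data.frame(scaffold = names(scaffolds)[host], marker = markers,
               start = start, end = start + len - 1L,
               score = round(stats::runif(length(markers), 50, 500), 1),
               stringsAsFactors = FALSE)
}

#' Simulate a complete two-sample community
#'
#' Runs the whole generator under a single seed: genome sequences,
#' scaffold fragmentation, per-base depth per sample, planted marker
#' hits, a paired-end link graph connecting adjacent scaffolds of each
#' genome, and the ground-truth tables. The global seed fans out to
#' fixed per-stage, per-genome seeds, so the output is byte-identical
#' for identical spec + seed.
#'
#' @param spec a \linkS4class{CommunitySpec}.
#' @param seed integer seed.
#' @param noise depth noise model (\code{"poisson"} or \code{"none"}).
#' @param minLen minimum scaffold length (default 500).
#' @param readLength read length (bp) used to convert aligned bases to
#'   aligned-read counts (default 100).
#' @param concentration Dirichlet concentration for the per-genome
#'   composition perturbation (default 50).
#' @return a \linkS4class{SyntheticCommunity}.
#' @export
simulateCommunity <- function(spec, seed = 1L, noise = "poisson",
                              minLen = 500, readLength = 100,
                              concentration = 50) {
    methods::validObject(spec)
    g <- spec@genomes
    samples <- spec@samples
    covCols <- paste0("cov_", samples)
    scafList <- vector("list", nrow(g))
    truthList <- vector("list", nrow(g))
    hitList <- vector("list", nrow(g))
    linkList <- vector("list", nrow(g))
    depthList <- lapply(samples, function(s) vector("list", nrow(g)))
    names(depthList) <- samples

    for (i in seq_len(nrow(g))) {
        set.seed(.stageSeed(seed, "sequence") + i)
        genome <- generateGenome(g$length[i], g$gc[i], g$markovOrder[i],
                                 concentration = concentration)
        set.seed(.stageSeed(seed, "fragment") + i)
        sc <- fragmentGenome(genome, g$fragMean[i], g$fragSigma[i],
                             minLen = minLen, prefix = g$name[i])
        scafList[[i]] <- sc
        truthList[[i]] <- data.frame(scaffold = names(sc),
                                     genome = g$name[i],
                                     stringsAsFactors = FALSE)
        for (k in seq_along(samples)) {
            set.seed(.stageSeed(seed, "depth") + 2L * i + k)
            depthList[[samples[k]]][[i]] <-
                simulateDepth(sc, g[[covCols[k]]][i], noise = noise)
        }
        set.seed(.stageSeed(seed, "markers") + i)
        hitList[[i]] <- plantMarkers(sc, g$nMarkers[i], g$nDuplicated[i])
        if (length(sc) > 1) {
            set.seed(.stageSeed(seed, "links") + i)
            nm <- names(sc)
            linkList[[i]] <- data.frame(
                a = nm[-length(nm)], b = nm[-1],
                weight = 2L + stats::rpois(length(nm) - 1L, 5),
                stringsAsFactors = FALSE)
        }
    }

    allScaf <- do.call(c, scafList)
    depth <- lapply(depthList, function(l) do.call(rbind, l))
    aligned <- vapply(depth, function(d) sum(as.numeric(d$depth)),
                      numeric(1)) / readLength
    methods::new("SyntheticCommunity",
                 scaffolds = allScaf,
                 depth = depth,
                 truth = do.call(rbind, truthList),
                 markerHits = do.call(rbind, hitList),
                 links = do.call(rbind, linkList),
                 alignedReads = aligned,
                 spec = spec, seed = as.integer(seed))
}

#' The default 13-genome two-condition community
#'
#' A community emulating the dominant populations of a grape-berry
#' surface metagenome sequenced after traditional (TW) and accelerated
#' (AW) post-harvest withering: 13 genomes whose dominant-sample
#' coverages, GC content, scaffold counts and essential-gene counts
#' follow the study's recovered draft genomes, with strongly skewed
#' two-sample coverage (fold-ratios from 20x up to 4000x). Genome
#' lengths are scaled by \code{scale} (default 0.1) to keep simulation
#' at desk scale while preserving scaffold counts, GC and coverage
#' structure.
#'
#' @param scale length scaling factor in (0, 1] (default 0.1).
#' @return a \linkS4class{CommunitySpec} with samples \code{TW},
#'   \code{AW}.
#' @export
witheringCommunitySpec <- function(scale = 0.1) {
    stopifnot(scale > 0, scale <= 1)
    g <- data.frame(
        name = c("clostridium01", "clostridium02", "lactobacillales03",
                 "erwinia04", "pantoea05", "pantoea06", "pseudomonas07",
                 "pseudomonas08", "pseudomonas09", "paenibacillus10",
                 "paenibacillus11", "actinomycetales12", "pseudomonas13"),
        length = c(4456330, 5268949, 3864387, 4663534, 4663534, 4234112,
                   8444622, 4540557, 4145951, 5684618, 6879406, 3863727,
                   3898344),
        gc = c(0.309, 0.291, 0.423, 0.547, 0.550, 0.554, 0.606, 0.592,
               0.592, 0.409, 0.459, 0.639, 0.604),
        nScaffolds = c(112, 103, 270, 173, 189, 172, 233, 177, 224, 57,
                       70, 246, 96),
        # dominant-sample mean coverage; the other sample is derived
        # from the study's stated fold-ratios (see vignette)
        cov_TW = c(2521.4 / 2400, 2521.4 / 2200, 645474.2 / 4000,
                   137.2 / 100, 1448.1 / 740, 8.6, 630.3, 97, 274.4,
                   5042.8, 5042.8, 4390, 207.9),
        cov_AW = c(2521.4, 2521.4, 645474.2, 137.2, 1448.1, 8.6 / 20,
                   630.3 / 50, 97 / 50, 274.4 / 50, 5042.8 / 4000,
                   5042.8 / 3600, 4390 / 3700, 207.9 / 50),
        nMarkers = c(105, 105, 72, 80, 40, 89, 66, 68, 14, 68, 104, 80,
                     75),
        nDuplicated = 0L,
        markovOrder = 1L,
        stringsAsFactors = FALSE)
    g$length <- as.integer(round(g$length * scale))
    g$fragMean <- pmax(500, round(g$length / g$nScaffolds))
    g$fragSigma <- 0.5
    g$nScaffolds <- NULL
    CommunitySpec(g, samples = c("TW", "AW"))
}

#' Write a simulated community to disk
#'
#' Emits scaffolds as FASTA, per-base depth as 3-column BED-style TSV
#' (scaffold, 0-based position, depth) per sample, marker hits, the
#' link graph and the truth table as TSV. File contents are
#' byte-deterministic for a given community.
#'
#' @param community a \linkS4class{SyntheticCommunity}.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
writeCommunity <- function(community, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(fasta = file.path(dir, "scaffolds.fasta"))
    Biostrings::writeXStringSet(scaffolds(community), paths["fasta"])
    for (s in names(depthTables(community))) {
        p <- file.path(dir, sprintf("depth_%s.tsv", s))
        utils::write.table(depthTables(community)[[s]], p, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        paths[paste0("depth_", s)] <- p
    }
    tabs <- list(truth = truthTable(community),
                 marker_hits = markerHits(community),
                 links = linkGraph(community))
    for (nm in names(tabs)) {
        p <- file.path(dir, paste0(nm, ".tsv"))
        utils::write.table(tabs[[nm]], p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths[nm] <- p
    }
    p <- file.path(dir, "aligned_reads.tsv")
    utils::write.table(
        data.frame(sample = names(alignedReads(community)),
                   alignedReads = alignedReads(community)),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["aligned_reads"] <- p
    invisible(paths)
}
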