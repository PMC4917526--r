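# Differential-coverage bin seeding, composition refinement, paired-end
# link recovery, bin filtering and bin statistics.
#
# The study's original bin selection was interactive (scaffolds colored
# by taxonomy in a coverage-coverage plot); an automated, deterministic
# replacement is used here: density-based clustering in
# (log10(cov1 + eps), log10(cov2 + eps)) space, followed by a
# per-cluster secondary density clustering on tetranucleotide-PCA
# scores to separate genomes that share a coverage signature.

## Deterministic DBSCAN. Core points are found first, connected into
## components (order-independent), then each non-core point joins the
## cluster of its nearest core neighbour within eps. Cluster ids are
## canonicalized by each cluster's lexicographically smallest member,
## so permuting the input rows never changes the labelling.
.dbscan <- function(x, eps, minPts) {
    n <- nrow(x)
    lab <- rep(NA_integer_, n)
    if (n == 0) return(lab)
    d <- as.matrix(stats::dist(x))
    nb <- d <= eps
    core <- rowSums(nb) >= minPts       # includes self
    if (any(core)) {
        # union-find over core points
        parent <- seq_len(n)
        find <- function(i) {
            while (parent[i] != i) {
                parent[i] <<- parent[parent[i]]
                i <- parent[i]
            }
            i
        }
        ci <- which(core)
        for (i in ci) {
            for (j in ci[nb[i, ci]]) {
                ri <- find(i); rj <- find(j)
                if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
            }
        }
        roots <- vapply(ci, find, integer(1))
        comp <- match(roots, sort(unique(roots)))
        lab[ci] <- comp
        # border points: nearest core neighbour within eps
        for (i in which(!core)) {
            cand <- ci[nb[i, ci]]
            if (length(cand))
                lab[i] <- lab[cand[which.min(d[i, cand])]]
        }
    }
    # canonical ids: order clusters by smallest member rowname
    if (any(!is.na(lab))) {
        nms <- rownames(x)
        if (is.null(nms)) nms <- sprintf("%09d", seq_len(n))
        firsts <- tapply(nms, lab, min)       # names = provisional ids
        newId <- rank(firsts, ties.method = "first")
        lab <- as.integer(newId[as.character(lab)])
    }
    as.integer(lab)
}

#' Seed genome bins from two-sample differential coverage
#'
#' Scaffolds are clustered in (log10(cov_1 + pseudocount),
#' log10(cov_2 + pseudocount)) space using deterministic density-based
#' clustering; genomes with distinct abundance profiles across the two
#' conditions fall into distinct clusters.
#'
#' @param cov a normalized \linkS4class{CoverageMatrix}.
#' @param scaffoldLengths named numeric of scaffold lengths (bp).
#' @param minLen scaffolds shorter than this are left unassigned
#'   (default 500).
#' @param eps clustering radius in log10-coverage units (default 0.06).
#' @param minPts minimum neighbours (including self) for a core point
#'   (default 5).
#' @param pseudocount added before log10 so zero-coverage scaffolds are
#'   admissible (default 0.1).
#' @return named character vector: scaffold id -> bin label
#'   (\code{"cov<k>"}) or \code{NA} for noise/short scaffolds.
#' @export
seedBins <- function(cov, scaffoldLengths, minLen = 500, eps = 0.06,
                     minPts = 5, pseudocount = 0.1) {
    m <- normalizedCoverage(cov)
    labels <- stats::setNames(rep(NA_character_, nrow(m)), rownames(m))
    if (all(m == 0)) {
        warning("all-zero coverage matrix; no bins seeded")
        return(labels)
    }
    use <- rownames(m)[scaffoldLengths[rownames(m)] >= minLen]
    x <- log10(m[use, , drop = FALSE] + pseudocount)
    cl <- .dbscan(x, eps = eps, minPts = minPts)
    labels[use[!is.na(cl)]] <- sprintf("cov%02d", cl[!is.na(cl)])
    labels
}

#' Refine coverage bins by tetranucleotide composition
#'
#' Within each seeded coverage cluster, a PCA of the members'
#' tetranucleotide frequencies is computed and a secondary density
#' clustering on the first \code{nComponents} scores splits
#' multi-species clusters. A split is accepted only when at least two
#' children have >= \code{minChild} scaffolds (members of sub-noise or
#' undersized children stay with the nearest accepted child). Clusters
#' are never merged and no scaffold changes its seeded cluster.
#'
#' @param labels named label vector from \code{\link{seedBins}}.
#' @param tnf TNF matrix from \code{\link{tnfMatrix}} covering all
#'   labelled scaffolds.
#' @param nComponents PCA components used (default 3).
#' @param eps density radius on the score scale (default 0.004, in TNF
#'   frequency units).
#' @param minPts minimum neighbours for a core point (default 8).
#' @param minChild minimum child size for an accepted split (default 5).
#' @return named character vector of refined labels; split bins get
#'   suffixed labels (\code{"cov03.1"}, \code{"cov03.2"}, ...).
#' @export
refineBins <- function(labels, tnf, nComponents = 3, eps = 0.004,
                       minPts = 8, minChild = 5) {
    assigned <- names(labels)[!is.na(labels)]
    missing <- setdiff(assigned, rownames(tnf))
    if (length(missing))
        stop("TNF matrix does not cover all seeded scaffolds (first: ",
             missing[1], ")")
    out <- labels
    for (bin in sort(unique(labels[!is.na(labels)]))) {
        members <- names(labels)[!is.na(labels) & labels == bin]
        if (length(members) < 2 * minChild) next
        sub <- tnf[members, , drop = FALSE]
        ok <- !apply(sub, 1, anyNA)
        if (sum(ok) < 2 * minChild) next
        k <- min(nComponents, sum(ok) - 1L)
        proj <- projectTnf(sub[ok, , drop = FALSE], k)
        sc <- proj@scores
        cl <- .dbscan(sc, eps = eps, minPts = minPts)
        sizes <- table(cl)
        keep <- as.integer(names(sizes)[sizes >= minChild])
        if (length(keep) < 2) next
        # attach sub-noise / undersized children to nearest kept centroid
        cent <- vapply(keep, function(kk)
            colMeans(sc[which(cl == kk), , drop = FALSE]), numeric(ncol(sc)))
        cent <- matrix(cent, ncol = length(keep))
        child <- integer(nrow(sc))
        for (i in seq_len(nrow(sc))) {
            if (!is.na(cl[i]) && cl[i] %in% keep)
                child[i] <- match(cl[i], keep)
            else
                child[i] <- which.min(colSums((cent - sc[i, ])^2))
        }
        newLab <- sprintf("%s.%d", bin, child)
        out[rownames(sc)] <- newLab
        # members whose TNF was undefined keep the largest child
        if (any(!ok)) {
            main <- names(sort(table(newLab), decreasing = TRUE))[1]
            out[members[!ok]] <- main
        }
    }
    out
}

#' Recruit unbinned scaffolds through paired-end links
#'
#' A noise scaffold joins bin B iff the summed link weight to members
#' of B is >= \code{minWeight} and B is the unique maximum; ties leave
#' the scaffold unassigned. One deterministic pass over the noise
#' scaffolds, evaluated against the input labels (recruited scaffolds
#' do not themselves recruit).
#'
#' @param labels named label vector (\code{NA} = unbinned).
#' @param links data.frame with columns \code{a}, \code{b},
#'   \code{weight} (undirected paired-end link counts, >= 1).
#' @param minWeight minimum total link weight to join (default 3).
#' @return the augmented label vector.
#' @export
recoverLinked <- function(labels, links, minWeight = 3) {
    if (minWeight < 1) stop("minWeight must be >= 1")
    if (is.null(links) || nrow(links) == 0) return(labels)
    stopifnot(all(c("a", "b", "weight") %in% names(links)))
    edges <- rbind(
        data.frame(from = links$a, to = links$b, w = links$weight,
                   stringsAsFactors = FALSE),
        data.frame(from = links$b, to = links$a, w = links$weight,
                   stringsAsFactors = FALSE))
    noise <- names(labels)[is.na(labels)]
    rel <- edges[edges$from %in% noise, , drop = FALSE]
    rel$bin <- labels[rel$to]
    rel <- rel[!is.na(rel$bin), , drop = FALSE]
    if (!nrow(rel)) return(labels)
    agg <- stats::aggregate(w ~ from + bin, data = rel, FUN = sum)
    out <- labels
    for (s in unique(agg$from)) {
        rows <- agg[agg$from == s, , drop = FALSE]
        best <- max(rows$w)
        if (best >= minWeight && sum(rows$w == best) == 1L)
            out[s] <- rows$bin[which.max(rows$w)]
    }
    out
}

#' Per-bin assembly statistics
#'
#' @param labels named label vector (scaffold -> bin, \code{NA}
#'   ignored).
#' @param scaffolds named \code{DNAStringSet} of scaffold sequences.
#' @param cov a normalized \linkS4class{CoverageMatrix}.
#' @param which \code{"normalized"} (default) or \code{"raw"}.
#' @return data.frame with one row per bin: \code{bin},
#'   \code{nScaffolds}, \code{totalLength}, \code{gcPercent}
#'   (length-weighted), and one length-weighted mean coverage column
#'   per sample (\code{cov_<sample>}).
#' @export
binStats <- function(labels, scaffolds, cov,
                     which = c("normalized", "raw")) {
    which <- match.arg(which)
    m <- if (which == "normalized") normalizedCoverage(cov) else
        rawCoverage(cov)
    keep <- !is.na(labels)
    if (!any(keep)) stop("no scaffold is assigned to any bin")
    ids <- names(labels)[keep]
    bad <- setdiff(ids, names(scaffolds))
    if (length(bad)) stop("binned scaffold missing from scaffold set: ",
                          bad[1])
    bad <- setdiff(ids, rownames(m))
    if (length(bad)) stop("binned scaffold missing from coverage matrix: ",
                          bad[1])
    w <- Biostrings::width(scaffolds[ids])
    gcBases <- Biostrings::letterFrequency(scaffolds[ids], "GC")[, 1]
    bin <- labels[keep]
    len <- rowsum(as.numeric(w), bin)
    gc <- rowsum(gcBases, bin)
    covW <- rowsum(m[ids, , drop = FALSE] * w, bin)
    out <- data.frame(bin = rownames(len),
                      nScaffolds = as.integer(table(bin)[rownames(len)]),
                      totalLength = len[, 1],
                      gcPercent = 100 * gc[, 1] / len[, 1],
                      stringsAsFactors = FALSE, row.names = NULL)
    for (s in colnames(m))
        out[[paste0("cov_", s)]] <- covW[, s] / len[, 1]
    out[order(out$bin), , drop = FALSE]
}

#' Filter genome bins on completeness and size
#'
#' A bin is rejected only when it is BOTH poorly complete and small:
#' completeness below \code{minCompleteness} AND total length below
#' \code{minSize}. (A large bin of low completeness is a partially
#' recovered genome and is kept.)
#'
#' @param stats data.frame from \code{\link{binStats}}.
#' @param census data.frame from \code{\link{markerCensus}}.
#' @param minCompleteness percentage threshold (default 20).
#' @param minSize bp threshold (default 1e6).
#' @return list with \code{kept} (stats rows + \code{completeness}
#'   column) and \code{rejected} (bin, completeness, totalLength,
#'   reason).
#' @export
filterBins <- function(stats, census, minCompleteness = 20,
                       minSize = 1e6) {
    idx <- match(stats$bin, census$bin)
    if (anyNA(idx))
        stop("census missing for bin(s): ",
             paste(stats$bin[is.na(idx)], collapse = ", "))
    comp <- completeness(census$uniqueMarkers[idx],
                         census$refSize[idx])
    stats$completeness <- comp
    reject <- comp < minCompleteness & stats$totalLength < minSize
    rejected <- data.frame(
        bin = stats$bin[reject], completeness = comp[reject],
        totalLength = stats$totalLength[reject],
        reason = sprintf("completeness %d%% < %g%% and size %d bp < %g bp",
                         comp[reject], minCompleteness,
                         as.integer(stats$totalLength[reject]), minSize),
        stringsAsFactors = FALSE)
    list(kept = stats[!reject, , drop = FALSE], rejected = rejected)
}

#' Compare predicted bins with a ground truth
#'
#' @param labels named label vector (scaffold -> bin, \code{NA} =
#'   unbinned).
#' @param truth named character vector (scaffold -> source genome) or a
#'   truth data.frame with columns \code{scaffold}, \code{genome}.
#' @param purityThreshold a genome counts as recovered when some
#'   cluster has it as majority genome with purity >= this value
#'   (default 0.9).
#' @return list: \code{clusters} (per-cluster size, majority genome,
#'   purity), \code{recoveredGenomes}, \code{nRecovered},
#'   \code{assignedFraction}.
#' @export
evaluateBinning <- function(labels, truth, purityThreshold = 0.9) {
    if (is.data.frame(truth))
        truth <- stats::setNames(truth$genome, truth$scaffold)
    keep <- !is.na(labels)
    df <- data.frame(bin = labels[keep],
                     genome = truth[names(labels)[keep]],
                     stringsAsFactors = FALSE)
    cl <- lapply(split(df$genome, df$bin), function(gs) {
        tab <- sort(table(gs), decreasing = TRUE)
        data.frame(size = length(gs), majorityGenome = names(tab)[1],
                   purity = as.numeric(tab[1]) / length(gs),
                   stringsAsFactors = FALSE)
    })
    clusters <- do.call(rbind, cl)
    clusters <- data.frame(bin = names(cl), clusters,
                           stringsAsFactors = FALSE, row.names = NULL)
    rec <- unique(clusters$majorityGenome[
        clusters$purity >= purityThreshold])
    list(clusters = clusters, recoveredGenomes = rec,
         nRecovered = length(rec),
         assignedFraction = mean(keep))
}
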