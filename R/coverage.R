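# Per-scaffold mean coverage per sample, cross-sample normalization by
# aligned-read counts, and coverage-weighted functional-category
# abundance.

#' Mean per-base coverage of each scaffold
#'
#' Positions absent from the depth table count as depth 0 (the sparse
#' bedtools-genomecov convention), so the mean is the total depth
#' divided by the full scaffold length.
#'
#' @param depth data.frame with columns \code{scaffold}, \code{pos}
#'   (0-based) and \code{depth} (non-negative integers).
#' @param scaffoldLengths named numeric of scaffold lengths (bp); every
#'   scaffold in \code{depth} must be present.
#' @return named numeric of mean coverages, one entry per scaffold in
#'   \code{scaffoldLengths} (0 for scaffolds without depth records).
#' @export
meanCoverage <- function(depth, scaffoldLengths) {
    stopifnot(all(c("scaffold", "pos", "depth") %in% names(depth)))
    if (is.null(names(scaffoldLengths)))
        stop("scaffoldLengths must be named by scaffold id")
    unknown <- setdiff(unique(depth$scaffold), names(scaffoldLengths))
    if (length(unknown))
        stop("depth records for scaffolds of unknown length: ",
             paste(utils::head(unknown, 5), collapse = ", "))
    if (any(depth$depth < 0)) stop("depths must be >= 0")
    if (any(depth$pos < 0)) stop("positions must be >= 0")
    over <- depth$pos >= scaffoldLengths[depth$scaffold]
    if (any(over))
        stop(sum(over), " depth record(s) with position >= scaffold length",
             " (first: ", depth$scaffold[which(over)[1]], " pos ",
             depth$pos[which(over)[1]], ")")
    out <- stats::setNames(numeric(length(scaffoldLengths)),
                           names(scaffoldLengths))
    if (nrow(depth)) {
        sums <- rowsum(as.numeric(depth$depth), group = depth$scaffold)
        out[rownames(sums)] <- sums[, 1]
    }
    out / scaffoldLengths
}

#' Build a CoverageMatrix from per-sample depth tables
#'
#' @param depthList named list of two depth tables (see
#'   \code{\link{meanCoverage}}), one per sample.
#' @param scaffoldLengths named numeric of scaffold lengths.
#' @param alignedReads named numeric, aligned-read count per sample.
#' @return a \linkS4class{CoverageMatrix} (raw only; apply
#'   \code{\link{normalizeCoverage}} before binning).
#' @export
coverageFromDepth <- function(depthList, scaffoldLengths, alignedReads) {
    stopifnot(length(depthList) == 2L, !is.null(names(depthList)))
    raw <- vapply(depthList, meanCoverage, numeric(length(scaffoldLengths)),
                  scaffoldLengths = scaffoldLengths)
    if (is.null(dim(raw)))  # single scaffold
        raw <- matrix(raw, nrow = 1, dimnames = list(
            names(scaffoldLengths), names(depthList)))
    methods::new("CoverageMatrix", raw = raw,
                 alignedReads = alignedReads[colnames(raw)])
}

#' Construct a CoverageMatrix from precomputed mean coverages
#'
#' @param raw matrix (scaffolds x 2 samples) of raw mean coverages,
#'   with scaffold rownames and sample colnames.
#' @param alignedReads named numeric, aligned-read count per sample.
#' @return a \linkS4class{CoverageMatrix}.
#' @export
CoverageMatrix <- function(raw, alignedReads) {
    methods::new("CoverageMatrix", raw = raw,
                 alignedReads = alignedReads[colnames(raw)])
}

#' Normalize coverage across samples by aligned-read counts
#'
#' Each sample is scaled by min(aligned reads) / (its aligned reads), so
#' the sample with fewer aligned reads is the reference and keeps its
#' raw coverage. Normalization is idempotent when aligned counts are
#' equal.
#'
#' @param cov a \linkS4class{CoverageMatrix}.
#' @return the matrix with the \code{normalized} slot filled.
#' @export
normalizeCoverage <- function(cov) {
    ar <- cov@alignedReads
    if (any(ar <= 0)) stop("aligned-read counts must be > 0")
    factors <- min(ar) / ar
    cov@normalized <- sweep(cov@raw, 2, factors[colnames(cov@raw)], `*`)
    methods::validObject(cov)
    cov
}

#' Coverage-weighted functional-category abundance
#'
#' For one sample, sums the (normalized) coverage of each gene's host
#' scaffold within every functional category; a gene annotated with k
#' categories contributes to k rows.
#'
#' @param genes data.frame with columns \code{gene}, \code{scaffold},
#'   \code{category}; multiple labels may be packed into one field
#'   separated by \code{","} or \code{";"}.
#' @param cov a normalized \linkS4class{CoverageMatrix}.
#' @param sample which sample column to use.
#' @param which \code{"normalized"} (default) or \code{"raw"} coverage.
#' @return data.frame with one row per category: \code{category},
#'   \code{nGenes}, \code{abundance} (summed host-scaffold coverage) and
#'   \code{meanCoverage} (= abundance / nGenes).
#' @export
functionalAbundance <- function(genes, cov, sample,
                                which = c("normalized", "raw")) {
    which <- match.arg(which)
    stopifnot(all(c("gene", "scaffold", "category") %in% names(genes)))
    m <- if (which == "normalized") normalizedCoverage(cov) else
        rawCoverage(cov)
    if (!sample %in% colnames(m))
        stop("unknown sample: ", sample)
    unknown <- setdiff(unique(genes$scaffold), rownames(m))
    if (length(unknown))
        stop("gene(s) on scaffolds absent from the coverage matrix: ",
             paste(utils::head(unknown, 5), collapse = ", "))
    labs <- strsplit(as.character(genes$category), "[,;]\\s*")
    expanded <- data.frame(
        category = unlist(labs),
        coverage = rep(m[genes$scaffold, sample], lengths(labs)),
        stringsAsFactors = FALSE)
    ab <- rowsum(expanded$coverage, group = expanded$category)
    n <- as.vector(table(expanded$category)[rownames(ab)])
    out <- data.frame(category = rownames(ab), nGenes = n,
                      abundance = ab[, 1],
                      meanCoverage = ab[, 1] / n,
                      stringsAsFactors = FALSE, row.names = NULL)
    out[order(out$category), , drop = FALSE]
}
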