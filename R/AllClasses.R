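#' @import methods
#' @importFrom Biostrings DNAStringSet
#' @importClassesFrom Biostrings DNAStringSet
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Two-sample synthetic community specification
#'
#' Describes a set of source genomes and the two samples (conditions) in
#' which they occur. Each genome row carries the parameters the simulator
#' needs: total length (bp), target GC fraction, Markov order of the
#' sequence model, per-sample mean coverage, how many of the reference
#' essential single-copy markers it carries (and how many of those are
#' duplicated), and the scaffold fragmentation model (lognormal mean
#' length and log-scale dispersion).
#'
#' @slot genomes data.frame with columns \code{name}, \code{length},
#'   \code{gc}, \code{markovOrder}, one coverage column per sample
#'   (named \code{cov_<sample>}), \code{nMarkers}, \code{nDuplicated},
#'   \code{fragMean}, \code{fragSigma}.
#' @slot samples character vector of exactly two sample identifiers.
#'
#' @exportClass CommunitySpec
setClass("CommunitySpec",
    representation(genomes = "data.frame", samples = "character"))

setValidity("CommunitySpec", function(object) {
    g <- object@genomes
    msg <- character()
    if (length(object@samples) != 2L)
        msg <- c(msg, "exactly 2 samples are required")
    if (anyDuplicated(object@samples))
        msg <- c(msg, "sample identifiers must be distinct")
    covCols <- paste0("cov_", object@samples)
    need <- c("name", "length", "gc", "markovOrder", covCols,
              "nMarkers", "nDuplicated", "fragMean", "fragSigma")
    miss <- setdiff(need, names(g))
    if (length(miss))
        msg <- c(msg, paste("missing genome columns:",
                            paste(miss, collapse = ", ")))
    if (nrow(g) < 2L)
        msg <- c(msg, "at least 2 genomes are required")
    if (length(msg)) return(msg)
    if (anyDuplicated(g$name))
        msg <- c(msg, "genome names must be unique")
    if (any(g$length <= 0))
        msg <- c(msg, "genome lengths must be positive")
    if (any(g$gc <= 0 | g$gc >= 1))
        msg <- c(msg, "gc targets must lie in (0, 1)")
    if (any(g$markovOrder < 1))
        msg <- c(msg, "markovOrder must be >= 1")
    if (any(as.matrix(g[, covCols]) < 0))
        msg <- c(msg, "per-sample coverages must be >= 0")
    if (any(g$nDuplicated > g$nMarkers))
        msg <- c(msg, "nDuplicated must not exceed nMarkers")
    if (any(g$length < 10 * g$fragMean))
        msg <- c(msg, "genome length must be >= 10 * mean scaffold length")
    if (length(msg)) msg else TRUE
})

#' A simulated two-sample metagenome community
#'
#' Holds everything the simulator emits: scaffold sequences, per-base
#' depth tables for both samples, planted marker hits, the paired-end
#' link graph, per-sample aligned-read counts, and the ground-truth
#' scaffold-to-genome assignment.
#'
#' @slot scaffolds \linkS4class{DNAStringSet} of scaffold sequences.
#' @slot depth named list (one element per sample) of data.frames with
#'   columns \code{scaffold}, \code{pos} (0-based), \code{depth}.
#' @slot truth data.frame with columns \code{scaffold}, \code{genome}.
#' @slot markerHits data.frame with columns \code{scaffold},
#'   \code{marker}, \code{start}, \code{end}, \code{score}.
#' @slot links data.frame with columns \code{a}, \code{b}, \code{weight}.
#' @slot alignedReads named numeric, aligned-read count per sample.
#' @slot spec the \linkS4class{CommunitySpec} that produced the object.
#' @slot seed integer seed used for the simulation.
#'
#' @exportClass SyntheticCommunity
setClass("SyntheticCommunity",
    representation(scaffolds = "DNAStringSet", depth = "list",
                   truth = "data.frame", markerHits = "data.frame",
                   links = "data.frame", alignedReads = "numeric",
                   spec = "CommunitySpec", seed = "integer"))

setValidity("SyntheticCommunity", function(object) {
    msg <- character()
    ids <- names(object@scaffolds)
    if (anyDuplicated(ids))
        msg <- c(msg, "scaffold ids must be unique")
    if (!setequal(ids, object@truth$scaffold) ||
        anyDuplicated(object@truth$scaffold))
        msg <- c(msg, "every scaffold must appear exactly once in the truth table")
    if (!identical(sort(names(object@depth)),
                   sort(object@spec@samples)))
        msg <- c(msg, "depth tables must cover exactly the two samples")
    if (length(msg)) msg else TRUE
})

#' Per-scaffold coverage across two samples
#'
#' Mean per-base depth of every scaffold in each sample, plus the
#' aligned-read counts used for cross-sample normalization. The
#' \code{normalized} slot is filled by \code{\link{normalizeCoverage}}:
#' each sample is scaled by min(aligned reads)/aligned reads, so the
#' sample with fewer aligned reads is the reference and keeps its raw
#' values.
#'
#' @slot raw matrix (scaffolds x samples) of raw mean coverages.
#' @slot normalized matrix of normalized coverages, or NULL before
#'   \code{normalizeCoverage} has been applied.
#' @slot alignedReads named numeric, aligned-read count per sample.
#'
#' @exportClass CoverageMatrix
setClass("CoverageMatrix",
    representation(raw = "matrix", normalized = "matrixOrNULL",
                   alignedReads = "numeric"),
    prototype(normalized = NULL))

setValidity("CoverageMatrix", function(object) {
    msg <- character()
    if (ncol(object@raw) != 2L)
        msg <- c(msg, "exactly 2 sample columns are required")
    if (is.null(colnames(object@raw)) || is.null(rownames(object@raw)))
        msg <- c(msg, "raw coverage must have scaffold rownames and sample colnames")
    if (any(object@raw < 0))
        msg <- c(msg, "coverages must be >= 0")
    if (!identical(sort(names(object@alignedReads)),
                   sort(colnames(object@raw))))
        msg <- c(msg, "alignedReads must be named by the sample columns")
    if (!is.null(object@normalized)) {
        if (!identical(dimnames(object@normalized), dimnames(object@raw)))
            msg <- c(msg, "normalized matrix must mirror the raw matrix")
        ref <- names(which.min(object@alignedReads))
        if (!isTRUE(all.equal(object@normalized[, ref], object@raw[, ref])))
            msg <- c(msg, "reference sample must keep its raw coverage")
    }
    if (length(msg)) msg else TRUE
})

#' Principal-component projection of tetranucleotide frequencies
#'
#' @slot scores matrix (scaffolds x components) of PCA scores.
#' @slot explainedVariance numeric fraction of variance per retained
#'   component (non-increasing).
#' @slot rotation loading matrix (136 canonical tetramers x components).
#' @slot center the column means removed before projection.
#'
#' @exportClass TnfProjection
setClass("TnfProjection",
    representation(scores = "matrix", explainedVariance = "numeric",
                   rotation = "matrix", center = "numeric"))

setValidity("TnfProjection", function(object) {
    msg <- character()
    ev <- object@explainedVariance
    if (length(ev) != ncol(object@scores))
        msg <- c(msg, "one explained-variance fraction per component required")
    if (any(diff(ev) > 1e-12))
        msg <- c(msg, "explained-variance fractions must be non-increasing")
    if (sum(ev) > 1 + 1e-8)
        msg <- c(msg, "explained-variance fractions must sum to <= 1")
    if (length(msg)) msg else TRUE
})
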