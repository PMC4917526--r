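#' @include AllClasses.R
NULL

#' Accessors for simulated communities and coverage matrices
#'
#' \code{scaffolds} returns the scaffold sequences; \code{truthTable} the
#' scaffold-to-genome ground truth; \code{markerHits} the planted marker
#' hit table; \code{linkGraph} the paired-end link graph;
#' \code{depthTables} the per-sample per-base depth tables;
#' \code{alignedReads} the per-sample aligned-read counts;
#' \code{rawCoverage}/\code{normalizedCoverage} the coverage matrices.
#'
#' @param x a \linkS4class{SyntheticCommunity} or
#'   \linkS4class{CoverageMatrix} object.
#' @return The slot contents (see the class documentation).
#' @name accessors
#' @aliases scaffolds truthTable markerHits linkGraph depthTables
#'   alignedReads rawCoverage normalizedCoverage
NULL

#' @rdname accessors
#' @export
setGeneric("scaffolds", function(x) standardGeneric("scaffolds"))

#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname accessors
#' @export
setGeneric("markerHits", function(x) standardGeneric("markerHits"))

#' @rdname accessors
#' @export
setGeneric("linkGraph", function(x) standardGeneric("linkGraph"))

#' @rdname accessors
#' @export
setGeneric("depthTables", function(x) standardGeneric("depthTables"))

#' @rdname accessors
#' @export
setGeneric("alignedReads", function(x) standardGeneric("alignedReads"))

#' @rdname accessors
#' @export
setGeneric("rawCoverage", function(x) standardGeneric("rawCoverage"))

#' @rdname accessors
#' @export
setGeneric("normalizedCoverage",
    function(x) standardGeneric("normalizedCoverage"))

setMethod("scaffolds", "SyntheticCommunity", function(x) x@scaffolds)
setMethod("truthTable", "SyntheticCommunity", function(x) x@truth)
setMethod("markerHits", "SyntheticCommunity", function(x) x@markerHits)
setMethod("linkGraph", "SyntheticCommunity", function(x) x@links)
setMethod("depthTables", "SyntheticCommunity", function(x) x@depth)
setMethod("alignedReads", "SyntheticCommunity", function(x) x@alignedReads)

setMethod("rawCoverage", "CoverageMatrix", function(x) x@raw)
setMethod("alignedReads", "CoverageMatrix", function(x) x@alignedReads)
setMethod("normalizedCoverage", "CoverageMatrix", function(x) {
    if (is.null(x@normalized))
        stop("coverage matrix has not been normalized; ",
             "call normalizeCoverage() first")
    x@normalized
})

setMethod("show", "CommunitySpec", function(object) {
    g <- object@genomes
    cat("CommunitySpec:", nrow(g), "genomes,",
        "samples:", paste(object@samples, collapse = ", "), "\n")
    cat("  total length:", format(sum(g$length), big.mark = ","), "bp;",
        "GC", sprintf("%.1f-%.1f%%", 100 * min(g$gc), 100 * max(g$gc)), "\n")
})

setMethod("show", "SyntheticCommunity", function(object) {
    cat("SyntheticCommunity:", length(object@scaffolds), "scaffolds from",
        nrow(object@spec@genomes), "genomes (seed", object@seed, ")\n")
    cat("  samples:", paste(object@spec@samples, collapse = ", "), "|",
        format(sum(Biostrings::width(object@scaffolds)), big.mark = ","),
        "bp |", nrow(object@markerHits), "planted marker hits\n")
})

setMethod("show", "CoverageMatrix", function(object) {
    cat("CoverageMatrix:", nrow(object@raw), "scaffolds x",
        ncol(object@raw), "samples",
        if (is.null(object@normalized)) "(raw only)" else "(normalized)",
        "\n")
    cat("  aligned reads:",
        paste(sprintf("%s=%s", names(object@alignedReads),
                      format(object@alignedReads, big.mark = ",")),
              collapse = ", "), "\n")
})

setMethod("show", "TnfProjection", function(object) {
    cat("TnfProjection:", nrow(object@scores), "scaffolds x",
        ncol(object@scores), "components; explained variance:",
        paste(sprintf("%.3f", object@explainedVariance), collapse = ", "),
        "\n")
})
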