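# Essential single-copy marker-gene census per bin: completeness and
# duplication. The default reference is an abstract list of 105 marker
# identifiers, the size of the essential-gene set used for Firmicutes,
# Gammaproteobacteria and Actinobacteria draft genomes; any id list can
# be plugged in.

#' The default essential single-copy marker reference set
#'
#' @param n number of markers (default 105).
#' @return character vector of marker ids.
#' @export
markerReference <- function(n = 105) {
    sprintf("ESG%03d", seq_len(n))
}

#' Census of marker hits per genome bin
#'
#' @param hits data.frame with columns \code{scaffold}, \code{marker}
#'   (and optionally \code{start}, \code{end}, \code{score}).
#' @param membership named character vector mapping scaffold id to bin
#'   id; \code{NA} marks unbinned scaffolds. Hits on scaffolds without a
#'   membership are ignored (their count is messaged).
#' @param reference character vector of valid marker ids.
#' @return data.frame with one row per bin (all bins occurring in
#'   \code{membership}, including empty ones): \code{bin},
#'   \code{uniqueMarkers}, \code{totalHits}, \code{duplicatedMarkers}
#'   (markers with >= 2 hits), \code{refSize}.
#' @export
markerCensus <- function(hits, membership, reference = markerReference()) {
    stopifnot(all(c("scaffold", "marker") %in% names(hits)) ||
              nrow(hits) == 0L)
    if (nrow(hits)) {
        bad <- setdiff(unique(hits$marker), reference)
        if (length(bad))
            stop("marker id(s) outside the reference set: ",
                 paste(utils::head(bad, 5), collapse = ", "))
    }
    bins <- sort(unique(membership[!is.na(membership)]))
    out <- data.frame(bin = bins, uniqueMarkers = 0L, totalHits = 0L,
                      duplicatedMarkers = 0L,
                      refSize = length(reference),
                      stringsAsFactors = FALSE)
    if (nrow(hits)) {
        hitBin <- membership[hits$scaffold]
        dropped <- is.na(hitBin) | !hits$scaffold %in% names(membership)
        if (any(dropped))
            message(sum(dropped),
                    " marker hit(s) on unassigned scaffolds ignored")
        kept <- hits[!dropped, , drop = FALSE]
        hitBin <- hitBin[!dropped]
        if (nrow(kept)) {
            tab <- table(bin = hitBin, marker = kept$marker)
            idx <- match(rownames(tab), out$bin)
            out$uniqueMarkers[idx] <- as.integer(rowSums(tab > 0))
            out$totalHits[idx] <- as.integer(rowSums(tab))
            out$duplicatedMarkers[idx] <- as.integer(rowSums(tab >= 2))
        }
    }
    out
}

#' Genome-bin completeness from a marker census
#'
#' Percentage of the reference marker set detected in a bin, rounded
#' half-up to an integer.
#'
#' @param unique number of distinct markers found (vectorized).
#' @param refSize reference set size (default 105).
#' @return integer percentage(s).
#' @examples
#' completeness(72)   # 69
#' completeness(40)   # 38
#' @export
completeness <- function(unique, refSize = 105) {
    if (any(unique < 0 | unique > refSize))
        stop("unique marker count must lie in [0, refSize]")
    as.integer(roundHalfUp(100 * unique / refSize, 0))
}

#' Duplication level of each bin
#'
#' Single-copy markers appearing more than once indicate contamination
#' or strain mixture. Two summaries are reported: the count of markers
#' with >= 2 hits, and the ratio of total hits to distinct markers
#' (1.0 when strictly single-copy; 0 for bins without markers).
#'
#' @param census data.frame from \code{\link{markerCensus}}.
#' @return data.frame with columns \code{bin}, \code{duplicatedMarkers},
#'   \code{duplicationRatio}.
#' @export
duplicationLevel <- function(census) {
    ratio <- ifelse(census$uniqueMarkers == 0, 0,
                    census$totalHits / census$uniqueMarkers)
    data.frame(bin = census$bin,
               duplicatedMarkers = census$duplicatedMarkers,
               duplicationRatio = ratio, stringsAsFactors = FALSE)
}
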