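# Read- and annotation-accounting arithmetic: the bookkeeping percentages
# a two-sample shotgun study reports (QC losses, host contamination,
# annotation match rates).

#' Percentage of a count, rounded half-up
#'
#' @param numerator non-negative count.
#' @param denominator positive count.
#' @param decimals decimal places to keep (default 2).
#' @return 100 * numerator / denominator rounded half-up to
#'   \code{decimals} places.
#' @examples
#' percentOf(223038, 89280038)        # 0.25
#' percentOf(58555, 89280038, 3)      # 0.066
#' @export
percentOf <- function(numerator, denominator, decimals = 2) {
    if (any(denominator <= 0))
        stop("denominator must be > 0")
    if (any(numerator < 0))
        stop("numerator must be >= 0")
    roundHalfUp(100 * numerator / denominator, decimals)
}

#' Per-sample read-accounting report
#'
#' Summarises, for each sequencing sample, the fraction of reads removed
#' by quality control and the fraction aligning to the host (plant)
#' genome. Retained and removed fractions are complementary at full
#' precision; the printed columns are rounded half-up.
#'
#' @param stats data.frame with columns \code{sample}, \code{totalReads},
#'   \code{qcRemoved} and optionally \code{hostAligned}.
#' @param decimals decimals for the QC percentages (default 2).
#' @param hostDecimals decimals for the host percentage (default 3).
#' @return data.frame with one row per sample: rounded
#'   \code{removedPct}, \code{retainedPct}, \code{hostPct}, plus an
#'   attribute \code{"exact"} holding the unrounded fractions.
#' @export
qcReport <- function(stats, decimals = 2, hostDecimals = 3) {
    need <- c("sample", "totalReads", "qcRemoved")
    if (!all(need %in% names(stats)))
        stop("stats must have columns: ", paste(need, collapse = ", "))
    if (!"hostAligned" %in% names(stats))
        stats$hostAligned <- NA_real_
    with(stats, {
        if (any(qcRemoved < 0 | qcRemoved > totalReads))
            stop("qcRemoved must lie in [0, totalReads]")
        if (any(!is.na(hostAligned) &
                (hostAligned < 0 | hostAligned > totalReads)))
            stop("hostAligned must lie in [0, totalReads]")
    })
    removedExact <- 100 * stats$qcRemoved / stats$totalReads
    hostExact <- 100 * stats$hostAligned / stats$totalReads
    out <- data.frame(
        sample = stats$sample,
        totalReads = stats$totalReads,
        removedPct = roundHalfUp(removedExact, decimals),
        retainedPct = roundHalfUp(100 - removedExact, decimals),
        hostPct = ifelse(is.na(hostExact), NA_real_,
                         roundHalfUp(hostExact, hostDecimals)),
        stringsAsFactors = FALSE)
    attr(out, "exact") <- data.frame(
        sample = stats$sample, removedPct = removedExact,
        retainedPct = 100 - removedExact, hostPct = hostExact,
        stringsAsFactors = FALSE)
    out
}

#' Annotation match rates across databases
#'
#' @param totalGenes number of predicted protein-coding genes.
#' @param matched named integer vector, genes matched per database.
#' @param decimals decimals to keep (default 1).
#' @return named numeric vector of percentages.
#' @examples
#' annotationCoverage(86425, c(COG = 57333, BLASTp = 76407))
#' @export
annotationCoverage <- function(totalGenes, matched, decimals = 1) {
    if (totalGenes <= 0) stop("totalGenes must be > 0")
    if (any(matched > totalGenes))
        stop("matched counts cannot exceed totalGenes")
    if (any(matched < 0)) stop("matched counts must be >= 0")
    vapply(matched, percentOf, numeric(1),
           denominator = totalGenes, decimals = decimals)
}
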