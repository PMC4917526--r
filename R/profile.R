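# Rank-level relative-abundance profiles from clade tables (lineage
# strings in the k__/p__/c__ dialect) and two-condition comparison.

#' Roll a clade table up to one taxonomic rank
#'
#' Abundances (read counts or pre-normalized percentages; both work
#' because columns are renormalized) are summed within each clade at
#' the requested rank and scaled to 100 per sample.
#'
#' @param clades data.frame whose first column holds lineage strings
#'   (\code{"k__Bacteria;p__Proteobacteria;..."}) and remaining columns
#'   per-sample abundances (>= 0).
#' @param rank one of kingdom, phylum, class, order, family, genus,
#'   species; every lineage must reach this rank.
#' @return data.frame: \code{clade} (the lineage truncated at
#'   \code{rank}, so the profile can itself be rolled up again) plus
#'   one relative-abundance column per sample, each column summing to
#'   100 (when nonzero); the rank is kept in attribute \code{"rank"}.
#' @export
rollupProfile <- function(clades, rank) {
    rank <- match.arg(rank, names(.RANKS))
    if (ncol(clades) < 2)
        stop("clade table needs a lineage column and >= 1 sample column")
    sampleCols <- names(clades)[-1]
    vals <- as.matrix(clades[, sampleCols, drop = FALSE])
    if (any(vals < 0)) stop("abundances must be >= 0")
    at <- character(nrow(clades))
    for (i in seq_len(nrow(clades))) {
        parsed <- tryCatch(parseLineage(clades[[1]][i]), error = function(e)
            stop("row ", i, ": ", conditionMessage(e), call. = FALSE))
        if (!rank %in% names(parsed))
            stop("row ", i, ": lineage '", clades[[1]][i],
                 "' lacks rank ", rank)
        at[i] <- .truncateLineage(parsed, rank)
    }
    sums <- rowsum(vals, group = at)
    rel <- apply(sums, 2, function(col)
        if (sum(col) > 0) 100 * col / sum(col) else col)
    rel <- matrix(rel, nrow = nrow(sums), dimnames = dimnames(sums))
    out <- data.frame(clade = rownames(rel), rel, stringsAsFactors = FALSE,
                      row.names = NULL, check.names = FALSE)
    out <- out[order(out$clade), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "rank") <- rank
    out
}

#' Compare two rank profiles (e.g. two conditions)
#'
#' @param profileA,profileB data.frames with columns \code{clade} and
#'   \code{abundance} (or a single sample column), carrying a
#'   \code{"rank"} attribute as produced by \code{\link{rollupProfile}}
#'   (subset to one sample with \code{\link{profileColumn}}).
#' @param pseudocount added to both sides of the ratio so clades absent
#'   from one sample yield finite ratios (default 1e-4, on the percent
#'   scale).
#' @return data.frame per clade (union of both profiles):
#'   \code{clade}, \code{abundanceA}, \code{abundanceB},
#'   \code{pattern} (\code{shared}, \code{A-only}, \code{B-only},
#'   \code{absent}), \code{difference} (A - B), \code{ratio}.
#' @export
compareProfiles <- function(profileA, profileB, pseudocount = 1e-4) {
    ra <- attr(profileA, "rank")
    rb <- attr(profileB, "rank")
    if (!is.null(ra) && !is.null(rb) && !identical(ra, rb))
        stop("profiles are at different ranks: ", ra, " vs ", rb)
    valcol <- function(p) {
        stopifnot("clade" %in% names(p), ncol(p) >= 2)
        stats::setNames(p[[2]], p$clade)
    }
    a <- valcol(profileA)
    b <- valcol(profileB)
    clades <- sort(union(names(a), names(b)))
    av <- ifelse(clades %in% names(a), a[clades], 0)
    bv <- ifelse(clades %in% names(b), b[clades], 0)
    pattern <- ifelse(av > 0 & bv > 0, "shared",
               ifelse(av > 0, "A-only",
               ifelse(bv > 0, "B-only", "absent")))
    data.frame(clade = clades, abundanceA = av, abundanceB = bv,
               pattern = pattern, difference = av - bv,
               ratio = (av + pseudocount) / (bv + pseudocount),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Extract one sample from a rank profile
#'
#' @param profile a rank profile from \code{\link{rollupProfile}}.
#' @param sample name of the sample column.
#' @return two-column data.frame (\code{clade}, \code{abundance}) with
#'   the rank attribute preserved.
#' @export
profileColumn <- function(profile, sample) {
    if (!sample %in% names(profile))
        stop("unknown sample column: ", sample)
    out <- data.frame(clade = profile$clade,
                      abundance = profile[[sample]],
                      stringsAsFactors = FALSE)
    attr(out, "rank") <- attr(profile, "rank")
    out
}
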