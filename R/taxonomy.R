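# Taxonomic assignment of genome bins from essential-gene identity
# evidence: nucleotide best-hit identity thresholds (>=95% species,
# >=85% genus, >=75% phylum), with protein-similarity and phylogenomic
# placement used as a fallback consensus when nucleotide identity is
# too low for a genus call.

#' Mean best-hit identity of a bin's essential genes
#'
#' Genes without a hit (NA identity) are excluded from the mean and
#' counted separately; scoring them 0 would bias bins of poorly
#' represented taxa downwards.
#'
#' @param evidence data.frame with columns \code{bin}, \code{gene},
#'   \code{ntIdentity}, \code{aaIdentity} (identities in [0, 100] or
#'   NA for no hit).
#' @return data.frame per bin: \code{bin}, \code{meanNtIdentity},
#'   \code{meanAaIdentity}, \code{nGenes}, \code{nNoNtHit},
#'   \code{nNoAaHit}.
#' @export
meanIdentity <- function(evidence) {
    stopifnot(all(c("bin", "gene", "ntIdentity", "aaIdentity") %in%
                  names(evidence)))
    if (nrow(evidence) == 0) stop("no identity evidence supplied")
    rng <- c(evidence$ntIdentity, evidence$aaIdentity)
    if (any(rng < 0 | rng > 100, na.rm = TRUE))
        stop("identities must lie in [0, 100]")
    res <- lapply(split(evidence, evidence$bin), function(e) {
        data.frame(
            bin = e$bin[1],
            meanNtIdentity = if (all(is.na(e$ntIdentity))) NA_real_
                             else mean(e$ntIdentity, na.rm = TRUE),
            meanAaIdentity = if (all(is.na(e$aaIdentity))) NA_real_
                             else mean(e$aaIdentity, na.rm = TRUE),
            nGenes = nrow(e),
            nNoNtHit = sum(is.na(e$ntIdentity)),
            nNoAaHit = sum(is.na(e$aaIdentity)),
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    if (all(is.na(out$meanNtIdentity)) && all(is.na(out$meanAaIdentity)))
        warning("no gene in any bin has a hit; means are all NA")
    out
}

#' Rank from mean nucleotide identity
#'
#' Inclusive thresholds: >= 95 species, >= 85 genus, >= 75 phylum;
#' below 75 no call is made (fallback evidence is then consulted).
#'
#' @param identity mean nucleotide identity in [0, 100] (vectorized).
#' @return character: \code{"species"}, \code{"genus"},
#'   \code{"phylum"} or \code{NA} (no call).
#' @examples
#' assignRank(c(98.1, 87.8, 75, 74.999))
#' @export
assignRank <- function(identity) {
    if (any(identity < 0 | identity > 100, na.rm = TRUE))
        stop("identity must lie in [0, 100]")
    ifelse(is.na(identity), NA_character_,
    ifelse(identity >= 95, "species",
    ifelse(identity >= 85, "genus",
    ifelse(identity >= 75, "phylum", NA_character_))))
}

#' Consensus taxonomic assignment for one bin
#'
#' The nucleotide identity call is used directly when it reaches genus
#' or species. Otherwise protein-similarity and phylogenomic-placement
#' lineages are combined: the call is the deepest rank at which they
#' agree (placement confidence must be \code{"high"} or
#' \code{"medium"}); a disagreement therefore resolves to the
#' shallowest common ancestor. With only one fallback source, its own
#' deepest rank is used. A phylum-level nucleotide call acts as a floor
#' under the fallback result.
#'
#' @param bin bin identifier.
#' @param ntIdentity mean nucleotide identity (may be NA).
#' @param ntLineage representative nucleotide best-hit lineage string.
#' @param aaIdentity mean protein identity (may be NA).
#' @param aaLineage protein best-hit lineage string (may be NA).
#' @param placementLineage phylogenomic placement lineage (may be NA).
#' @param placementConfidence one of \code{"high"}, \code{"medium"},
#'   \code{"low"}, \code{"incomplete"} or NA.
#' @return one-row data.frame: \code{bin}, \code{rank}, \code{lineage},
#'   \code{method} (\code{nucleotide}, \code{protein},
#'   \code{placement} or \code{consensus}), \code{meanNtIdentity},
#'   \code{meanAaIdentity}.
#' @export
consensusTaxonomy <- function(bin, ntIdentity = NA, ntLineage = NA,
                              aaIdentity = NA, aaLineage = NA,
                              placementLineage = NA,
                              placementConfidence = NA) {
    hasNt <- !is.na(ntIdentity) && !is.na(ntLineage)
    hasAa <- !is.na(aaLineage)
    placeOk <- !is.na(placementLineage) &&
        !is.na(placementConfidence) &&
        placementConfidence %in% c("high", "medium")
    if (!hasNt && !hasAa && !placeOk)
        stop("no taxonomic evidence for bin ", bin)

    result <- function(rank, lineage, method)
        data.frame(bin = bin, rank = rank, lineage = lineage,
                   method = method, meanNtIdentity = ntIdentity,
                   meanAaIdentity = aaIdentity, stringsAsFactors = FALSE)

    ntRank <- if (!is.na(ntIdentity)) assignRank(ntIdentity) else
        NA_character_
    if (hasNt && !is.na(ntRank) && ntRank %in% c("species", "genus")) {
        pl <- parseLineage(ntLineage)
        return(result(ntRank, .truncateLineage(pl, ntRank), "nucleotide"))
    }

    fallback <- NULL
    if (hasAa && placeOk) {
        a <- parseLineage(aaLineage)
        p <- parseLineage(placementLineage)
        depth <- .deepestAgreement(a, p)
        if (depth >= 1) {
            rank <- names(.RANKS)[depth]
            fallback <- result(rank, .truncateLineage(a, rank),
                               "consensus")
        }
    } else if (hasAa) {
        a <- parseLineage(aaLineage)
        rank <- names(.RANKS)[length(a)]
        fallback <- result(rank, .truncateLineage(a, rank), "protein")
    } else if (placeOk) {
        p <- parseLineage(placementLineage)
        rank <- names(.RANKS)[length(p)]
        fallback <- result(rank, .truncateLineage(p, rank), "placement")
    }

    ntFloor <- if (hasNt && !is.na(ntRank)) {
        pl <- parseLineage(ntLineage)
        result(ntRank, .truncateLineage(pl, ntRank), "nucleotide")
    } else NULL

    pick <- function(x) match(x$rank, names(.RANKS))
    if (!is.null(fallback) &&
        (is.null(ntFloor) || pick(fallback) >= pick(ntFloor)))
        return(fallback)
    if (!is.null(ntFloor)) return(ntFloor)
    stop("no taxonomic evidence deep enough for bin ", bin)
}

#' Assign taxonomy to every bin from an evidence table
#'
#' Convenience driver: computes per-bin mean identities, picks the
#' modal nucleotide/protein best-hit lineage per bin, and applies
#' \code{\link{consensusTaxonomy}}.
#'
#' @param evidence data.frame with columns \code{bin}, \code{gene},
#'   \code{ntIdentity}, \code{ntLineage}, \code{aaIdentity},
#'   \code{aaLineage}.
#' @param placements optional data.frame with columns \code{bin},
#'   \code{lineage}, \code{confidence}.
#' @return data.frame with one row per bin (see
#'   \code{\link{consensusTaxonomy}}).
#' @export
assignTaxonomy <- function(evidence, placements = NULL) {
    means <- meanIdentity(evidence)
    modal <- function(x) {
        x <- x[!is.na(x)]
        if (!length(x)) return(NA_character_)
        tab <- sort(table(x), decreasing = TRUE)
        names(tab)[1]
    }
    rows <- lapply(seq_len(nrow(means)), function(i) {
        b <- means$bin[i]
        e <- evidence[evidence$bin == b, , drop = FALSE]
        pl <- if (!is.null(placements) && b %in% placements$bin)
            placements[placements$bin == b, , drop = FALSE][1, ] else NULL
        consensusTaxonomy(
            bin = b,
            ntIdentity = means$meanNtIdentity[i],
            ntLineage = modal(e$ntLineage),
            aaIdentity = means$meanAaIdentity[i],
            aaLineage = modal(e$aaLineage),
            placementLineage = if (is.null(pl)) NA else pl$lineage,
            placementConfidence = if (is.null(pl)) NA else pl$confidence)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
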