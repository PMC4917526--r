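# Shared helpers: decimal rounding and lineage-string handling.

#' Round half away from zero to a fixed number of decimals
#'
#' Unlike \code{round()}, which rounds half to even, values exactly on a
#' .5 boundary are rounded up. Used wherever a printed percentage is
#' reproduced.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    # nudge by an epsilon proportional to x to undo binary representation
    # error on exact .5 boundaries (e.g. 0.265 stored as 0.26499999...)
    floor(x * p + 0.5 + sign(x) * .Machine$double.eps * abs(x) * p) / p
}

## ordered taxonomic ranks and their lineage-string prefixes
.RANKS <- c(kingdom = "k__", phylum = "p__", class = "c__", order = "o__",
            family = "f__", genus = "g__", species = "s__")

#' Parse a rank-prefixed lineage string
#'
#' Accepts the usual \code{"k__Bacteria;p__Proteobacteria;..."} dialect.
#'
#' @param lineage a single lineage string.
#' @return named character vector, names in rank order (kingdom deepest
#'   first); only the ranks present are returned.
#' @export
parseLineage <- function(lineage) {
    stopifnot(is.character(lineage), length(lineage) == 1L)
    parts <- strsplit(trimws(lineage), ";", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    pref <- substr(parts, 1, 3)
    bad <- !pref %in% .RANKS
    if (any(bad))
        stop("malformed lineage field(s): ", paste(parts[bad], collapse = ", "))
    out <- substr(parts, 4, nchar(parts))
    names(out) <- names(.RANKS)[match(pref, .RANKS)]
    if (is.unsorted(match(names(out), names(.RANKS))))
        stop("lineage ranks out of order in: ", lineage)
    out
}

## deepest rank (by index into .RANKS) at which two parsed lineages agree;
## 0 when they do not even share a kingdom
.deepestAgreement <- function(a, b) {
    depth <- 0L
    for (i in seq_along(.RANKS)) {
        r <- names(.RANKS)[i]
        if (is.na(a[r]) || is.na(b[r]) || !nzchar(a[r] %||% "") ||
            a[r] != b[r])
            break
        depth <- i
    }
    depth
}

.truncateLineage <- function(parsed, rank) {
    keep <- names(.RANKS)[seq_len(match(rank, names(.RANKS)))]
    parsed <- parsed[intersect(keep, names(parsed))]
    paste0(.RANKS[names(parsed)], parsed, collapse = ";")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

## fixed per-stage seed fan-out from one global seed
.stageSeed <- function(seed, stage) {
    offsets <- c(sequence = 101L, fragment = 211L, depth = 307L,
                 markers = 401L, links = 503L)
    (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}
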