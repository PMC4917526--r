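# Canonical tetranucleotide frequency (TNF) signatures and their PCA.
#
# Assembled scaffolds have arbitrary strand, so a 4-mer and its reverse
# complement are counted together: 256 raw words collapse to 136
# canonical classes (16 palindromes + 120 reverse-complement pairs).

#' Names of the 136 canonical tetramers
#'
#' Canonical representative = lexicographic minimum of a 4-mer and its
#' reverse complement; the vector is ordered lexicographically by
#' representative.
#'
#' @return character vector of length 136.
#' @export
canonicalTetramers <- function() {
    .tnfCollapse()$canon
}

## collapse map from the 256 lexicographic 4-mers to canonical classes
.tnfCollapse <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        bases <- c("A", "C", "G", "T")
        words <- apply(expand.grid(bases, bases, bases, bases)[, 4:1],
                       1, paste, collapse = "")
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(words)))
        canonAll <- pmin(words, rc)
        canon <- sort(unique(canonAll))
        cache <<- list(words = words, index = match(canonAll, canon),
                       canon = canon)
        cache
    }
})

#' Canonical tetranucleotide frequency vectors
#'
#' Counts every length-4 sliding window (step 1); windows containing
#' non-ACGT symbols are skipped. A window and its reverse complement
#' increment the same canonical entry; counts are normalized by the
#' number of valid windows, so each row sums to 1.
#'
#' @param x a \code{DNAStringSet} (or anything coercible to one).
#' @return matrix (sequences x 136 canonical tetramers). Sequences with
#'   no valid window get an all-\code{NA} row and a warning; sequences
#'   with fewer than 50 valid windows are flagged in the logical
#'   attribute \code{"lowConfidence"}.
#' @export
tnfMatrix <- function(x) {
    if (!methods::is(x, "DNAStringSet"))
        x <- Biostrings::DNAStringSet(x)
    counts <- Biostrings::oligonucleotideFrequency(x, width = 4, step = 1)
    map <- .tnfCollapse()
    canonCounts <- t(rowsum(t(counts), group = map$index))
    colnames(canonCounts) <- map$canon
    rownames(canonCounts) <- names(x)
    valid <- rowSums(canonCounts)
    freq <- canonCounts / valid
    if (any(valid == 0)) {
        warning(sum(valid == 0),
                " sequence(s) have no valid 4-mer window; returning NA rows")
        freq[valid == 0, ] <- NA_real_
    }
    attr(freq, "nWindows") <- valid
    attr(freq, "lowConfidence") <- valid < 50
    freq
}

#' TNF vector of a single sequence
#'
#' @param x a single DNA sequence (character or \code{DNAString}).
#' @return named numeric vector of length 136 summing to 1.
#' @export
tnfVector <- function(x) {
    m <- tnfMatrix(Biostrings::DNAStringSet(as.character(x)))
    v <- m[1, ]
    if (anyNA(v))
        stop("sequence has no valid 4-mer window")
    v
}

#' Principal-component projection of a TNF matrix
#'
#' Column-centered PCA (no variance scaling: all entries share the
#' frequency scale). Component signs are fixed by making each
#' component's largest-magnitude loading positive, so the projection is
#' fully deterministic.
#'
#' @param tnf matrix as returned by \code{\link{tnfMatrix}}; \code{NA}
#'   rows are not allowed (exclude those scaffolds first).
#' @param nComponents number of components to retain (default 3).
#' @return a \linkS4class{TnfProjection}.
#' @export
projectTnf <- function(tnf, nComponents = 3) {
    if (anyNA(tnf))
        stop("tnf matrix contains NA rows; exclude undefined scaffolds")
    if (nrow(tnf) < nComponents + 1)
        stop("need at least nComponents + 1 scaffolds (",
             nComponents + 1, "), got ", nrow(tnf))
    p <- stats::prcomp(tnf, center = TRUE, scale. = FALSE)
    k <- min(nComponents, ncol(p$rotation))
    rot <- p$rotation[, seq_len(k), drop = FALSE]
    sco <- p$x[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
        i <- which.max(abs(rot[, j]))
        if (rot[i, j] < 0) {
            rot[, j] <- -rot[, j]
            sco[, j] <- -sco[, j]
        }
    }
    ev <- p$sdev^2 / sum(p$sdev^2)
    methods::new("TnfProjection", scores = sco,
                 explainedVariance = ev[seq_len(k)],
                 rotation = rot, center = p$center)
}
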