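# Readers and writers for the plain-text formats the pipeline consumes
# and emits: BED-style per-base depth TSV, scaffold length tables,
# coverage matrices, marker-hit tables (plain TSV or HMMER3
# tblout-style), link graphs and clade tables.

#' Read a BED-style per-base depth table
#'
#' Three tab-separated columns: scaffold, 0-based position, depth.
#' A header line is detected automatically.
#'
#' @param path file path.
#' @return data.frame with columns \code{scaffold}, \code{pos},
#'   \code{depth}.
#' @export
readDepthTable <- function(path) {
    first <- readLines(path, n = 1)
    header <- grepl("scaffold", first, fixed = TRUE)
    d <- utils::read.table(path, sep = "\t", header = header,
                           col.names = c("scaffold", "pos", "depth"),
                           colClasses = c("character", "integer",
                                          "integer"))
    d
}

#' Read a scaffold length table or FASTA
#'
#' @param path a two-column TSV (scaffold, length) or a FASTA file
#'   (detected by extension .fa/.fasta/.fna).
#' @return named numeric vector of lengths.
#' @export
readScaffoldLengths <- function(path) {
    if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) {
        x <- Biostrings::readDNAStringSet(path)
        return(stats::setNames(as.numeric(Biostrings::width(x)), names(x)))
    }
    first <- readLines(path, n = 1)
    header <- grepl("scaffold", first, fixed = TRUE)
    d <- utils::read.table(path, sep = "\t", header = header,
                           col.names = c("scaffold", "length"),
                           colClasses = c("character", "numeric"))
    stats::setNames(d$length, d$scaffold)
}

#' Read a marker-hit table
#'
#' @param path file path.
#' @param format \code{"tsv"} for the native 5-column table (scaffold,
#'   marker, start, end, score) or \code{"tblout"} for HMMER3-style
#'   space-separated tabular output (\code{#} comment lines skipped;
#'   column 1 = target scaffold, column 3 = marker/query name, column 6
#'   = score; coordinates are not part of tblout and are set to 0/1).
#' @return data.frame with columns \code{scaffold}, \code{marker},
#'   \code{start}, \code{end}, \code{score}.
#' @export
readMarkerHits <- function(path, format = c("tsv", "tblout")) {
    format <- match.arg(format)
    if (format == "tsv") {
        d <- utils::read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
        need <- c("scaffold", "marker", "start", "end", "score")
        miss <- setdiff(need, names(d))
        if (length(miss))
            stop("marker-hit table missing column(s): ",
                 paste(miss, collapse = ", "))
        return(d[, need])
    }
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    if (!length(lines))
        return(data.frame(scaffold = character(), marker = character(),
                          start = integer(), end = integer(),
                          score = numeric(), stringsAsFactors = FALSE))
    parts <- strsplit(trimws(lines), "[ \t]+")
    data.frame(
        scaffold = vapply(parts, `[`, "", 1L),
        marker = vapply(parts, `[`, "", 3L),
        start = 0L, end = 1L,
        score = as.numeric(vapply(parts, `[`, "", 6L)),
        stringsAsFactors = FALSE)
}

#' Read a paired-end link graph
#'
#' @param path three-column TSV: scaffold a, scaffold b, link weight.
#' @return data.frame with columns \code{a}, \code{b}, \code{weight}.
#' @export
readLinkGraph <- function(path) {
    first <- readLines(path, n = 1)
    header <- grepl("weight", first, fixed = TRUE)
    utils::read.table(path, sep = "\t", header = header,
                      col.names = c("a", "b", "weight"),
                      colClasses = c("character", "character",
                                     "numeric"))
}

#' Read a clade abundance table
#'
#' First column: lineage strings in the \code{k__...;p__...} dialect;
#' remaining columns: per-sample abundances (counts or percentages).
#'
#' @param path TSV path.
#' @return data.frame ready for \code{\link{rollupProfile}}.
#' @export
readCladeTable <- function(path) {
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
    if (ncol(d) < 2)
        stop("clade table needs a lineage column and >= 1 sample column")
    d
}

#' Write a CoverageMatrix as TSV
#'
#' @param cov a \linkS4class{CoverageMatrix}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCoverageMatrix <- function(cov, path) {
    raw <- rawCoverage(cov)
    d <- data.frame(scaffold = rownames(raw), raw, check.names = FALSE,
                    stringsAsFactors = FALSE)
    names(d)[-1] <- paste0("raw_", colnames(raw))
    if (!is.null(cov@normalized)) {
        nd <- as.data.frame(cov@normalized)
        names(nd) <- paste0("norm_", colnames(cov@normalized))
        d <- cbind(d, nd)
    }
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Validate input files and report diagnostics
#'
#' Non-throwing format checks with line-level diagnostics: duplicate
#' FASTA ids, negative depths, depth positions at or beyond the
#' scaffold length.
#'
#' @param fasta optional scaffold FASTA path.
#' @param depth optional depth TSV path (checked against \code{fasta}
#'   lengths when both are given).
#' @return data.frame of diagnostics (\code{file}, \code{line},
#'   \code{message}); zero rows when everything is clean.
#' @export
validateIO <- function(fasta = NULL, depth = NULL) {
    diag <- list()
    note <- function(file, line, message)
        diag[[length(diag) + 1L]] <<- data.frame(
            file = file, line = line, message = message,
            stringsAsFactors = FALSE)
    lengths <- NULL
    if (!is.null(fasta)) {
        lines <- readLines(fasta)
        hdr <- which(startsWith(lines, ">"))
        ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
        dups <- ids[duplicated(ids)]
        for (d in unique(dups))
            note(fasta, hdr[ids == d][2], paste0("duplicate id: ", d))
        x <- Biostrings::readDNAStringSet(fasta)
        lengths <- stats::setNames(Biostrings::width(x),
                                   sub("\\s.*$", "", names(x)))
    }
    if (!is.null(depth)) {
        d <- readDepthTable(depth)
        first <- readLines(depth, n = 1)
        off <- if (grepl("scaffold", first, fixed = TRUE)) 1L else 0L
        bad <- which(d$depth < 0)
        for (i in bad) note(depth, i + off, "negative depth")
        if (!is.null(lengths)) {
            known <- d$scaffold %in% names(lengths)
            for (i in which(!known)[seq_len(min(5, sum(!known)))])
                note(depth, i + off,
                     paste0("unknown scaffold: ", d$scaffold[i]))
            over <- which(known & d$pos >= lengths[d$scaffold])
            for (i in over)
                note(depth, i + off,
                     paste0("position ", d$pos[i],
                            " >= scaffold length ",
                            lengths[[d$scaffold[i]]]))
        }
    }
    if (!length(diag))
        return(data.frame(file = character(), line = integer(),
                          message = character(), stringsAsFactors = FALSE))
    do.call(rbind, diag)
}
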