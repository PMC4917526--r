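# End-to-end orchestration: simulate (or load) -> coverage -> TNF ->
# binning -> marker census -> filtering -> (taxonomy, profiles,
# accounting) -> consolidated bin report.

#' Assemble a run configuration
#'
#' @param spec a \linkS4class{CommunitySpec} driving the synthetic
#'   branch of the pipeline.
#' @param seed global integer seed, fanned out to fixed per-stage seeds.
#' @param outDir optional output directory; when given, all
#'   intermediates and the report are written there.
#' @param params named list of stage-parameter overrides. Recognised
#'   keys: \code{minLen}, \code{seedEps}, \code{seedMinPts},
#'   \code{pseudocount}, \code{refineEps}, \code{refineMinPts},
#'   \code{minChild}, \code{nComponents}, \code{linkMinWeight},
#'   \code{minCompleteness}, \code{minSize}, \code{noise}.
#' @param evidence optional taxonomy evidence table (see
#'   \code{\link{assignTaxonomy}}); bins named as in the final labels.
#' @param placements optional placement table for
#'   \code{\link{assignTaxonomy}}.
#' @param cladeTable optional clade abundance table (see
#'   \code{\link{rollupProfile}}).
#' @param profileRanks ranks at which \code{cladeTable} is rolled up
#'   (default phylum and class); every lineage must reach them.
#' @param readStats optional read-accounting table (see
#'   \code{\link{qcReport}}).
#' @return a validated configuration list of class \code{"dcbRunConfig"}.
#' @export
runConfig <- function(spec, seed = 1L, outDir = NULL, params = list(),
                      evidence = NULL, placements = NULL,
                      cladeTable = NULL, readStats = NULL,
                      profileRanks = c("phylum", "class")) {
    methods::validObject(spec)
    defaults <- list(minLen = 500, seedEps = 0.06, seedMinPts = 5,
                     pseudocount = 0.1, refineEps = 0.004,
                     refineMinPts = 8, minChild = 5, nComponents = 3,
                     linkMinWeight = 3, minCompleteness = 20,
                     minSize = 1e5, noise = "poisson")
    unknown <- setdiff(names(params), names(defaults))
    if (length(unknown))
        stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    defaults[names(params)] <- params
    structure(list(spec = spec, seed = as.integer(seed), outDir = outDir,
                   params = defaults, evidence = evidence,
                   placements = placements, cladeTable = cladeTable,
                   readStats = readStats, profileRanks = profileRanks),
              class = "dcbRunConfig")
}

#' Run the whole binning pipeline
#'
#' Stages: simulate the community; per-scaffold coverage and
#' normalization; TNF matrix; coverage seeding, TNF refinement and
#' link recovery; marker census; bin statistics and filtering; optional
#' taxonomy, rank profiles and read accounting. All numbers in the
#' report are recomputable from the persisted intermediates.
#'
#' @param config a configuration from \code{\link{runConfig}}.
#' @return (invisibly when writing to disk) a list with elements
#'   \code{community}, \code{coverage}, \code{labels}, \code{census},
#'   \code{stats}, \code{binReport}, \code{rejected}, \code{taxonomy},
#'   \code{profiles}, \code{accounting}, \code{evaluation}.
#' @export
runPipeline <- function(config) {
    if (!inherits(config, "dcbRunConfig"))
        stop("config must come from runConfig()")
    p <- config$params

    stage <- function(name, expr) {
        t0 <- proc.time()[["elapsed"]]
        res <- withCallingHandlers(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        message(sprintf("[%s] done in %.1fs", name,
                        proc.time()[["elapsed"]] - t0))
        res
    }

    community <- stage("simulate",
        simulateCommunity(config$spec, seed = config$seed,
                          noise = p$noise, minLen = p$minLen))
    scafs <- scaffolds(community)
    lens <- stats::setNames(as.numeric(Biostrings::width(scafs)),
                            names(scafs))

    cov <- stage("coverage", normalizeCoverage(coverageFromDepth(
        depthTables(community), lens, alignedReads(community))))

    tnf <- stage("tnf", tnfMatrix(scafs))

    labels <- stage("binning", {
        l <- seedBins(cov, lens, minLen = p$minLen, eps = p$seedEps,
                      minPts = p$seedMinPts, pseudocount = p$pseudocount)
        l <- refineBins(l, tnf, nComponents = p$nComponents,
                        eps = p$refineEps, minPts = p$refineMinPts,
                        minChild = p$minChild)
        recoverLinked(l, linkGraph(community),
                      minWeight = p$linkMinWeight)
    })

    census <- stage("markers",
        markerCensus(markerHits(community), labels))

    stats <- stage("stats", binStats(labels, scafs, cov))
    filtered <- filterBins(stats, census,
                           minCompleteness = p$minCompleteness,
                           minSize = p$minSize)

    taxonomy <- if (!is.null(config$evidence))
        stage("taxonomy", assignTaxonomy(config$evidence,
                                         config$placements)) else NULL
    profiles <- if (!is.null(config$cladeTable))
        stage("profile", stats::setNames(
            lapply(config$profileRanks, function(r)
                rollupProfile(config$cladeTable, r)),
            config$profileRanks)) else NULL
    accounting <- if (!is.null(config$readStats))
        stage("accounting", qcReport(config$readStats)) else NULL

    report <- .binReport(filtered$kept, census, taxonomy,
                         config$spec@samples)
    evaluation <- evaluateBinning(labels, truthTable(community))

    out <- list(community = community, coverage = cov, labels = labels,
                census = census, stats = stats, binReport = report,
                rejected = filtered$rejected, taxonomy = taxonomy,
                profiles = profiles, accounting = accounting,
                evaluation = evaluation)

    if (!is.null(config$outDir)) {
        .writeRunOutputs(out, community, config)
        return(invisible(out))
    }
    out
}

## consolidated per-bin report in the order: dataset of max coverage,
## bin, taxonomy, n scaffolds, total length, GC%, essential genes
## found/reference, completeness %, per-sample coverage, identities
.binReport <- function(kept, census, taxonomy, samples) {
    idx <- match(kept$bin, census$bin)
    covCols <- paste0("cov_", samples)
    dataset <- samples[max.col(as.matrix(kept[, covCols]),
                               ties.method = "first")]
    rep <- data.frame(
        dataset = dataset,
        bin = kept$bin,
        taxonomy = NA_character_,
        nScaffolds = kept$nScaffolds,
        totalLength = kept$totalLength,
        gcPercent = roundHalfUp(kept$gcPercent, 1),
        essentialGenes = sprintf("%d/%d", census$uniqueMarkers[idx],
                                 census$refSize[idx]),
        completeness = completeness(census$uniqueMarkers[idx],
                                    census$refSize[idx]),
        stringsAsFactors = FALSE)
    for (cc in covCols) rep[[cc]] <- roundHalfUp(kept[[cc]], 1)
    rep$meanAaIdentity <- NA_real_
    rep$meanNtIdentity <- NA_real_
    if (!is.null(taxonomy)) {
        ti <- match(rep$bin, taxonomy$bin)
        rep$taxonomy <- ifelse(is.na(ti), NA_character_,
                               taxonomy$lineage[ti])
        rep$meanAaIdentity <- taxonomy$meanAaIdentity[ti]
        rep$meanNtIdentity <- taxonomy$meanNtIdentity[ti]
    }
    rep[order(rep$bin), , drop = FALSE]
}

.writeRunOutputs <- function(out, community, config) {
    dir <- config$outDir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    hdr <- sprintf("# seed: %d", config$seed)
    writeTsv <- function(d, file) {
        path <- file.path(dir, file)
        con <- file(path, "w")
        writeLines(hdr, con)
        utils::write.table(d, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        close(con)
    }
    writeCommunity(community, file.path(dir, "community"))
    writeCoverageMatrix(out$coverage, file.path(dir, "coverage.tsv"))
    writeTsv(data.frame(scaffold = names(out$labels), bin = out$labels,
                        stringsAsFactors = FALSE), "membership.tsv")
    writeTsv(out$census, "marker_census.tsv")
    writeTsv(out$stats, "bin_stats.tsv")
    writeTsv(out$binReport, "bin_report.tsv")
    jsonlite::write_json(out$binReport,
                         file.path(dir, "bin_report.json"),
                         dataframe = "rows", na = "null", digits = NA,
                         pretty = TRUE)
    if (!is.null(out$taxonomy)) writeTsv(out$taxonomy, "taxonomy.tsv")
    if (!is.null(out$profiles))
        for (r in names(out$profiles))
            writeTsv(out$profiles[[r]], sprintf("profile_%s.tsv", r))
    if (!is.null(out$accounting)) writeTsv(out$accounting,
                                           "accounting.tsv")
    invisible(dir)
}
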