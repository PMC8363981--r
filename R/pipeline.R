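#' Run the full analysis pipeline
#'
#' Chains filtering, the per-group assortment scan, the two-group
#' comparison, and (optionally) gene annotation of the flagged SNPs, and
#' writes every artefact plus a run manifest into \code{outDir}:
#' \code{filter_report.json}, one \code{assort_<group>.tsv} per group,
#' \code{comparison.json} / \code{per_chromosome.tsv},
#' \code{annotation_<group>.tsv}, and \code{manifest.json}.
#'
#' Pair groups other than the two compared (for example mixed-origin
#' matings) are still scanned and written; only the comparison is limited
#' to \code{compare} groups.
#'
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @param pairsList named list of \linkS4class{MatePairSet} (as returned
#'   by [readMatePairs()]), or a single MatePairSet.
#' @param outDir output directory (created if needed).
#' @param filterConfig a \linkS4class{FilterConfig}; \code{NULL} skips
#'   filtering.
#' @param assortConfig an \linkS4class{AssortConfig}.
#' @param geneFeatures optional \code{GRanges} of genes for annotation.
#' @param compare character vector of two group labels to compare; default
#'   the first two groups present.
#' @param inputPaths optional named character vector of input file paths,
#'   recorded in the manifest with md5 digests.
#' @return invisibly, a list with \code{ge}, \code{report},
#'   \code{results} (per group), \code{comparison}, \code{annotation}.
#' @export
runPipeline <- function(ge, pairsList, outDir,
                        filterConfig = FilterConfig(),
                        assortConfig = AssortConfig(),
                        geneFeatures = NULL, compare = NULL,
                        inputPaths = character()) {
    t0 <- Sys.time()
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (is(pairsList, "MatePairSet"))
        pairsList <- setNames(list(pairsList), groupLabel(pairsList))
    timings <- list()

    report <- NULL
    if (!is.null(filterConfig)) {
        tf <- system.time(fc <- runFilterChain(ge, filterConfig))["elapsed"]
        ge <- fc$ge; report <- fc$report
        timings$filter <- unname(tf)
        jsonlite::write_json(as.list(report),
                             file.path(outDir, "filter_report.json"),
                             auto_unbox = TRUE, digits = NA)
    }

    results <- list()
    for (g in names(pairsList)) {
        ta <- system.time(
            res <- runGroupAssortment(pairsList[[g]], ge, assortConfig)
        )["elapsed"]
        timings[[paste0("assort_", g)]] <- unname(ta)
        results[[g]] <- res
        writeAssortResults(res, file.path(outDir,
                                          paste0("assort_", g, ".tsv")))
    }

    comparison <- NULL
    if (is.null(compare) && length(results) >= 2L)
        compare <- names(results)[1:2]
    if (!is.null(compare) && all(compare %in% names(results))) {
        comparison <- compareGroups(results[[compare[1]]],
                                    results[[compare[2]]],
                                    labelA = compare[1],
                                    labelB = compare[2])
        writeGroupComparison(comparison,
                             jsonPath = file.path(outDir,
                                                  "comparison.json"),
                             tsvPath = file.path(outDir,
                                                 "per_chromosome.tsv"))
    }

    annotation <- NULL
    if (!is.null(geneFeatures)) {
        annotation <- lapply(results, function(res) {
            flagged <- res[res$classification %in%
                           c("negative", "positive"), , drop = FALSE]
            annotateSnps(flagged, geneFeatures)
        })
        for (g in names(annotation))
            writeAnnotation(annotation[[g]],
                            file.path(outDir,
                                      paste0("annotation_", g, ".tsv")))
    }

    manifest <- list(
        package_version = as.character(packageVersion("MateAssort")),
        r_version = R.version.string,
        timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
        seed = assortConfig@seed,
        n_permutations = assortConfig@nPermutations,
        cutoffs = c(assortConfig@lowerCutoff, assortConfig@upperCutoff),
        null_scheme = assortConfig@nullScheme,
        groups = names(pairsList),
        compared = compare,
        n_sites_analysed = nrow(ge),
        n_individuals = ncol(ge),
        filter = if (is.null(report)) NULL else as.list(report),
        input_digests = if (length(inputPaths))
            as.list(tools::md5sum(inputPaths)) else NULL,
        stage_seconds = timings)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(list(ge = ge, report = report, results = results,
                   comparison = comparison, annotation = annotation))
}
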