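#' Filter-chain thresholds
#'
#' Constructor for \linkS4class{FilterConfig}. Defaults mirror common
#' practice for reduced-representation SNP data: drop individuals with more
#' than 20\% missing genotypes, sites whose mean depth is below 5 or above
#' 30, sites with more than 80\% missing data, and HDplot-flagged paralogs
#' (heterozygosity above 0.6 or read-ratio deviation outside [-5, 7]).
#' Set a threshold to \code{NA} to disable its stage.
#'
#' @param maxIndividualMissing,minMeanDepth,maxMeanDepth,maxSiteMissing,hdMaxHeterozygosity,hdMinD,hdMaxD
#'   thresholds; see \linkS4class{FilterConfig}.
#' @param depthMissing \code{"exclude"} (default) computes each site's mean
#'   depth over individuals with a non-missing genotype only; \code{"zero"}
#'   includes missing-genotype individuals, counting absent depth as 0.
#' @return a \linkS4class{FilterConfig}.
#' @export
FilterConfig <- function(maxIndividualMissing = 0.20,
                         minMeanDepth = 5, maxMeanDepth = 30,
                         maxSiteMissing = 0.80,
                         hdMaxHeterozygosity = 0.6,
                         hdMinD = -5, hdMaxD = 7,
                         depthMissing = c("exclude", "zero")) {
    new("FilterConfig",
        maxIndividualMissing = as.numeric(maxIndividualMissing),
        minMeanDepth = as.numeric(minMeanDepth),
        maxMeanDepth = as.numeric(maxMeanDepth),
        maxSiteMissing = as.numeric(maxSiteMissing),
        hdMaxHeterozygosity = as.numeric(hdMaxHeterozygosity),
        hdMinD = as.numeric(hdMinD), hdMaxD = as.numeric(hdMaxD),
        depthMissing = match.arg(depthMissing))
}

#' Filter-chain report
#'
#' Constructor for \linkS4class{FilterReport}. \code{nSitesOut}, if omitted,
#' is computed as \code{nSitesIn} minus the per-stage removals; supplying an
#' inconsistent value is an error.
#'
#' @param nSitesIn sites entering the chain.
#' @param nIndividualsRemoved individuals dropped for missingness.
#' @param nSitesRemovedParalog,nSitesRemovedDepth,nSitesRemovedMissing
#'   sites removed at each stage (each site counted once, at the first
#'   stage that removed it).
#' @param nSitesOut surviving sites; computed when \code{NULL}.
#' @param stageOrder character vector naming the stages in the order run.
#' @param removedIndividuals ids of dropped individuals.
#' @return a \linkS4class{FilterReport}.
#' @export
#' @examples
#' FilterReport(nSitesIn = 25658, nSitesRemovedDepth = 10204,
#'              nSitesRemovedMissing = 3)
FilterReport <- function(nSitesIn, nIndividualsRemoved = 0L,
                         nSitesRemovedParalog = 0L,
                         nSitesRemovedDepth = 0L,
                         nSitesRemovedMissing = 0L,
                         nSitesOut = NULL,
                         stageOrder = c("paralog", "individual_missing",
                                        "depth", "site_missing"),
                         removedIndividuals = character()) {
    if (is.null(nSitesOut))
        nSitesOut <- nSitesIn - nSitesRemovedParalog - nSitesRemovedDepth -
            nSitesRemovedMissing
    new("FilterReport", nSitesIn = as.integer(nSitesIn),
        nIndividualsRemoved = as.integer(nIndividualsRemoved),
        nSitesRemovedParalog = as.integer(nSitesRemovedParalog),
        nSitesRemovedDepth = as.integer(nSitesRemovedDepth),
        nSitesRemovedMissing = as.integer(nSitesRemovedMissing),
        nSitesOut = as.integer(nSitesOut),
        stageOrder = stageOrder,
        removedIndividuals = as.character(removedIndividuals))
}

#' @describeIn FilterReport sites surviving the chain.
#' @param report a \linkS4class{FilterReport}.
#' @export
nSitesOut <- function(report) report@nSitesOut

#' @describeIn FilterReport coerce the report to a named list (handy for
#'   JSON serialisation).
#' @export
setMethod("as.list", "FilterReport", function(x, ...) {
    list(n_sites_in = x@nSitesIn,
         n_individuals_removed = x@nIndividualsRemoved,
         n_sites_removed_paralog = x@nSitesRemovedParalog,
         n_sites_removed_depth = x@nSitesRemovedDepth,
         n_sites_removed_missing = x@nSitesRemovedMissing,
         n_sites_out = x@nSitesOut,
         stage_order = x@stageOrder,
         removed_individuals = x@removedIndividuals)
})

setMethod("show", "FilterReport", function(object) {
    cat("FilterReport\n")
    cat(sprintf("  sites in:                %7d\n", object@nSitesIn))
    cat(sprintf("  individuals removed:     %7d\n",
                object@nIndividualsRemoved))
    cat(sprintf("  sites removed (paralog): %7d\n",
                object@nSitesRemovedParalog))
    cat(sprintf("  sites removed (depth):   %7d\n",
                object@nSitesRemovedDepth))
    cat(sprintf("  sites removed (missing): %7d\n",
                object@nSitesRemovedMissing))
    cat(sprintf("  sites out:               %7d\n", object@nSitesOut))
    cat("  stage order:", paste(object@stageOrder, collapse = " -> "), "\n")
})

#' Permutation-test settings
#'
#' Constructor for \linkS4class{AssortConfig}. The defaults are 50000 null
#' replicates per locus with classification cutoffs at the 2.5th and 97.5th
#' percentile of the null; loci below the lower cutoff are negatively
#' assorting (mates less similar than random), loci above the upper cutoff
#' positively assorting.
#'
#' @param nPermutations,lowerCutoff,upperCutoff,minPairsPerLocus,seed,nullScheme,verbose
#'   see \linkS4class{AssortConfig}.
#' @return an \linkS4class{AssortConfig}.
#' @export
AssortConfig <- function(nPermutations = 50000L, lowerCutoff = 0.025,
                         upperCutoff = 0.975, minPairsPerLocus = 2L,
                         seed = 1L,
                         nullScheme = c("permute-males", "resample-males",
                                        "single-pairs"),
                         verbose = FALSE) {
    new("AssortConfig", nPermutations = as.integer(nPermutations),
        lowerCutoff = as.numeric(lowerCutoff),
        upperCutoff = as.numeric(upperCutoff),
        minPairsPerLocus = as.integer(minPairsPerLocus),
        seed = as.integer(seed), nullScheme = match.arg(nullScheme),
        verbose = isTRUE(verbose))
}

setMethod("show", "AssortConfig", function(object) {
    cat(sprintf(paste0("AssortConfig: %d permutations, cutoffs (%g, %g), ",
                       "min pairs %d, scheme '%s', seed %d\n"),
                object@nPermutations, object@lowerCutoff,
                object@upperCutoff, object@minPairsPerLocus,
                object@nullScheme, object@seed))
})

#' Synthetic-scenario settings
#'
#' Constructor for \linkS4class{SimConfig}. Defaults emulate one mating
#' group of the kind of coastal salmon cohort this analysis targets: 150
#' observed pairs drawn from 150 females and 150 males genotyped at 1000
#' biallelic SNPs, minor-allele frequencies uniform on [0.05, 0.5], 3\%
#' missing genotypes, and negative-binomial read depth with mean 15.
#'
#' @param nLoci,nFemales,nMales,nPairs,mafMin,mafMax,missingRate,depthMean,depthDispersion,paralogFraction,assortLoci,groupLabel,nChromosomes,seed
#'   see \linkS4class{SimConfig}.
#' @return a \linkS4class{SimConfig}.
#' @export
#' @examples
#' cfg <- SimConfig(nLoci = 50, nFemales = 10, nMales = 10, nPairs = 10)
SimConfig <- function(nLoci = 1000L, nFemales = 150L, nMales = 150L,
                      nPairs = 150L, mafMin = 0.05, mafMax = 0.5,
                      missingRate = 0.03, depthMean = 15,
                      depthDispersion = 5, paralogFraction = 0,
                      assortLoci = data.frame(locus = integer(),
                                              direction = character(),
                                              beta = numeric()),
                      groupLabel = "wild", nChromosomes = 30L, seed = 1L) {
    new("SimConfig", nLoci = as.integer(nLoci),
        nFemales = as.integer(nFemales), nMales = as.integer(nMales),
        nPairs = as.integer(nPairs), mafMin = as.numeric(mafMin),
        mafMax = as.numeric(mafMax), missingRate = as.numeric(missingRate),
        depthMean = as.numeric(depthMean),
        depthDispersion = as.numeric(depthDispersion),
        paralogFraction = as.numeric(paralogFraction),
        assortLoci = as.data.frame(assortLoci),
        groupLabel = as.character(groupLabel),
        nChromosomes = as.integer(nChromosomes), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0("SimConfig: %d loci on %d chromosomes, %dF x %dM, ",
                       "%d pairs, %d assorting loci, seed %d\n"),
                object@nLoci, object@nChromosomes, object@nFemales,
                object@nMales, object@nPairs, nrow(object@assortLoci),
                object@seed))
})

setMethod("show", "GroupComparison", function(object) {
    cat(sprintf("GroupComparison: %s vs %s\n",
                object@groupALabel, object@groupBLabel))
    cat(sprintf("  %-18s %10s %10s\n", "", "negative", "positive"))
    cat(sprintf("  %-18s %10d %10d\n", object@groupALabel,
                object@nNegativeA, object@nPositiveA))
    cat(sprintf("  %-18s %10d %10d\n", object@groupBLabel,
                object@nNegativeB, object@nPositiveB))
    cat(sprintf("  %-18s %6d (%.2f%%) %4d (%.2f%%)\n", "shared",
                object@sharedNegative,
                roundHalfUp(object@pctSharedNegative, 2),
                object@sharedPositive,
                roundHalfUp(object@pctSharedPositive, 2)))
    cat(sprintf("  same direction: %d, opposite direction: %d\n",
                object@sameDirection, object@oppositeDirection))
})

#' @describeIn GroupComparison coerce the comparison to a named list.
#' @param x a \linkS4class{GroupComparison}.
#' @param ... ignored.
#' @export
setMethod("as.list", "GroupComparison", function(x, ...) {
    list(group_a = x@groupALabel, group_b = x@groupBLabel,
         n_negative_a = x@nNegativeA, n_negative_b = x@nNegativeB,
         n_positive_a = x@nPositiveA, n_positive_b = x@nPositiveB,
         shared_negative = x@sharedNegative,
         shared_positive = x@sharedPositive,
         pct_shared_negative = x@pctSharedNegative,
         pct_shared_positive = x@pctSharedPositive,
         same_direction = x@sameDirection,
         opposite_direction = x@oppositeDirection)
})
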