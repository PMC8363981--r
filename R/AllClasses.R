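#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#'   elementNROWS queryHits subjectHits
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- assayNames rowRanges colData rowData rowData<-
#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom GenomeInfoDb seqnames
#' @importFrom BiocGenerics start end strand
#' @importFrom IRanges IRanges
#' @importFrom stats rbinom rmultinom rnbinom runif sd setNames
#' @importFrom utils read.table write.table packageVersion
NULL

.VALID_DOSAGE <- c(0L, 1L, 2L)

#' GenotypeExperiment: cohort genotypes at biallelic SNPs
#'
#' A \linkS4class{RangedSummarizedExperiment} holding a cohort of diploid
#' individuals (columns) genotyped at biallelic SNP loci (rows). The
#' \code{"dosage"} assay stores minor-allele dosage: 0, 1 or 2 copies of the
#' locus's minor allele, with \code{NA} for missing genotypes. Optional
#' \code{"refDepth"} and \code{"altDepth"} assays carry per-genotype read
#' counts for the reference and alternate allele, required by the depth and
#' paralog filters. Row metadata records each locus's \code{ref} and
#' \code{alt} alleles, whether the minor allele is the alternate
#' (\code{minorIsAlt}), and the minor-allele frequency (\code{maf}).
#' Column metadata is the cohort table: \code{sex} (\code{"female"} or
#' \code{"male"}) and \code{origin} (\code{"wild"}, \code{"hatchery"} or
#' \code{"unknown"}).
#'
#' @seealso [GenotypeExperiment()] the constructor,
#'   [encodeMinorAllele()], [readGenotypeVcf()]
#' @export
setClass("GenotypeExperiment",
    contains = "RangedSummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
    msg <- character()
    if (!"dosage" %in% assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- assay(object, "dosage")
        bad <- !is.na(d) & !(d %in% .VALID_DOSAGE)
        if (any(bad))
            msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
    }
    rd <- rowData(object)
    for (col in c("ref", "alt"))
        if (!col %in% colnames(rd))
            msg <- c(msg, sprintf("rowData column '%s' is required", col))
    hasRef <- "refDepth" %in% assayNames(object)
    hasAlt <- "altDepth" %in% assayNames(object)
    if (hasRef != hasAlt)
        msg <- c(msg, "refDepth and altDepth must be supplied together")
    if (hasRef && hasAlt) {
        rdp <- assay(object, "refDepth"); adp <- assay(object, "altDepth")
        if (any(rdp < 0, na.rm = TRUE) || any(adp < 0, na.rm = TRUE))
            msg <- c(msg, "allele depths must be non-negative")
    }
    cd <- colData(object)
    if ("sex" %in% colnames(cd)) {
        sx <- cd$sex
        if (!all(is.na(sx) | sx %in% c("female", "male")))
            msg <- c(msg, "sex must be 'female', 'male' or NA")
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "individual ids (colnames) must be unique")
    if (length(msg)) msg else TRUE
})

#' MatePairSet: observed mate pairs within one mating group
#'
#' An ordered set of (female, male) pairs carrying a single group label
#' (e.g. \code{"wild"} or \code{"hatchery"}). Pairs are unique as
#' combinations, but the same individual may appear in several pairs:
#' salmon mate multiply, and the permutation null samples males from the
#' multiset of males as they occur across pairs.
#'
#' @slot groupLabel single character group label.
#' @slot female,male character vectors of individual ids, one entry per pair.
#' @seealso [MatePairSet()], [readMatePairs()]
#' @export
setClass("MatePairSet",
    representation(groupLabel = "character",
                   female = "character",
                   male = "character"))

setValidity("MatePairSet", function(object) {
    msg <- character()
    if (length(object@groupLabel) != 1L)
        msg <- c(msg, "groupLabel must be a single string")
    if (length(object@female) != length(object@male))
        msg <- c(msg, "female and male must have equal length")
    if (anyDuplicated(paste(object@female, object@male, sep = "\r")))
        msg <- c(msg, "pairs must be unique (female, male) combinations")
    if (length(msg)) msg else TRUE
})

#' FilterConfig: thresholds for the post-calling filter chain
#'
#' Holds the thresholds applied, in order, by [runFilterChain()]:
#' HDplot paralog blacklisting, individual-level missingness, mean site
#' depth, and site-level missingness. Any threshold set to \code{NA}
#' disables its stage. All comparisons are strict: an individual is removed
#' when its missing fraction \emph{exceeds} \code{maxIndividualMissing}, a
#' site when its mean depth is \emph{below} \code{minMeanDepth} or
#' \emph{above} \code{maxMeanDepth}, or its missing fraction \emph{exceeds}
#' \code{maxSiteMissing}.
#'
#' @slot maxIndividualMissing fraction, default 0.20.
#' @slot minMeanDepth,maxMeanDepth mean read depth bounds, defaults 5 and 30.
#' @slot maxSiteMissing fraction, default 0.80.
#' @slot hdMaxHeterozygosity HDplot heterozygosity ceiling, default 0.6.
#' @slot hdMinD,hdMaxD HDplot read-ratio deviation bounds, defaults -5 and 7.
#' @slot depthMissing how individuals with a missing genotype enter the
#'   per-site mean depth: \code{"exclude"} (default) or \code{"zero"}.
#' @seealso [FilterConfig()], [runFilterChain()]
#' @export
setClass("FilterConfig",
    representation(maxIndividualMissing = "numeric",
                   minMeanDepth = "numeric",
                   maxMeanDepth = "numeric",
                   maxSiteMissing = "numeric",
                   hdMaxHeterozygosity = "numeric",
                   hdMinD = "numeric",
                   hdMaxD = "numeric",
                   depthMissing = "character"))

setValidity("FilterConfig", function(object) {
    msg <- character()
    frac <- c(maxIndividualMissing = object@maxIndividualMissing,
              maxSiteMissing = object@maxSiteMissing,
              hdMaxHeterozygosity = object@hdMaxHeterozygosity)
    bad <- !is.na(frac) & (frac < 0 | frac > 1)
    if (any(bad))
        msg <- c(msg, paste0(names(frac)[bad], " must lie in [0, 1]"))
    if (!is.na(object@minMeanDepth) && !is.na(object@maxMeanDepth) &&
        object@minMeanDepth > object@maxMeanDepth)
        msg <- c(msg, "minMeanDepth must not exceed maxMeanDepth")
    if (!is.na(object@hdMinD) && !is.na(object@hdMaxD) &&
        object@hdMinD > object@hdMaxD)
        msg <- c(msg, "hdMinD must not exceed hdMaxD")
    if (!object@depthMissing %in% c("exclude", "zero"))
        msg <- c(msg, "depthMissing must be 'exclude' or 'zero'")
    if (length(msg)) msg else TRUE
})

#' FilterReport: bookkeeping for one run of the filter chain
#'
#' Records how many sites entered the chain, how many were removed at each
#' stage (each site counted once, at the first stage that removed it) and
#' how many survived. The arithmetic identity
#' \code{nSitesOut == nSitesIn - paralog - depth - missing} is enforced at
#' construction.
#'
#' @seealso [FilterReport()], [runFilterChain()]
#' @export
setClass("FilterReport",
    representation(nSitesIn = "integer",
                   nIndividualsRemoved = "integer",
                   nSitesRemovedParalog = "integer",
                   nSitesRemovedDepth = "integer",
                   nSitesRemovedMissing = "integer",
                   nSitesOut = "integer",
                   stageOrder = "character",
                   removedIndividuals = "character"))

setValidity("FilterReport", function(object) {
    removed <- object@nSitesRemovedParalog + object@nSitesRemovedDepth +
        object@nSitesRemovedMissing
    if (object@nSitesOut != object@nSitesIn - removed)
        return("nSitesOut must equal nSitesIn minus the per-stage removals")
    if (any(c(object@nSitesIn, object@nIndividualsRemoved,
              object@nSitesRemovedParalog, object@nSitesRemovedDepth,
              object@nSitesRemovedMissing, object@nSitesOut) < 0L))
        return("all counts must be non-negative")
    TRUE
})

#' AssortConfig: settings for the per-locus permutation test
#'
#' @slot nPermutations number of null replicates per locus (default 50000).
#' @slot lowerCutoff,upperCutoff percentile cutoffs classifying a locus as
#'   negatively (below) or positively (above) assorting; defaults 0.025 and
#'   0.975.
#' @slot minPairsPerLocus minimum informative pairs for a locus to be
#'   classified (default 2).
#' @slot seed integer seed; per-locus RNG streams are derived from it so
#'   results do not depend on locus processing order.
#' @slot nullScheme \code{"permute-males"} (default): each replicate
#'   randomly re-matches the group's multiset of males to its females
#'   (a permutation of observed mates) and the null is the distribution of
#'   replicate mean scores; \code{"resample-males"}: every female is
#'   assigned a male drawn with replacement from the male multiset
#'   (conservative - the null then carries male-composition variance the
#'   observed statistic does not); \code{"single-pairs"}: the null is the
#'   distribution of single random pair scores, for sensitivity analysis.
#' @slot verbose logical, progress messages every 1000 loci.
#' @seealso [AssortConfig()], [runGroupAssortment()]
#' @export
setClass("AssortConfig",
    representation(nPermutations = "integer",
                   lowerCutoff = "numeric",
                   upperCutoff = "numeric",
                   minPairsPerLocus = "integer",
                   seed = "integer",
                   nullScheme = "character",
                   verbose = "logical"))

setValidity("AssortConfig", function(object) {
    msg <- character()
    if (object@nPermutations < 1L)
        msg <- c(msg, "nPermutations must be >= 1")
    if (!(object@lowerCutoff > 0 && object@lowerCutoff < object@upperCutoff &&
          object@upperCutoff < 1))
        msg <- c(msg, "need 0 < lowerCutoff < upperCutoff < 1")
    if (!object@nullScheme %in% c("permute-males", "resample-males",
                                  "single-pairs"))
        msg <- c(msg, "nullScheme must be 'permute-males', ",
                 "'resample-males' or 'single-pairs'")
    if (object@minPairsPerLocus < 1L)
        msg <- c(msg, "minPairsPerLocus must be >= 1")
    if (length(msg)) msg else TRUE
})

#' GroupComparison: overlap of two groups' flagged SNP sets
#'
#' Produced by [compareGroups()]. Shared counts are loci carrying the same
#' non-\code{"none"} classification in both groups; \code{sameDirection} is
#' their total and \code{oppositeDirection} counts loci flagged in both
#' groups with opposite signs. Shared percentages use the sum of the two
#' groups' flagged counts as denominator (see the package vignette for why
#' this convention, rather than the union, is used).
#'
#' @export
setClass("GroupComparison",
    representation(groupALabel = "character",
                   groupBLabel = "character",
                   nNegativeA = "integer",
                   nNegativeB = "integer",
                   nPositiveA = "integer",
                   nPositiveB = "integer",
                   sharedNegative = "integer",
                   sharedPositive = "integer",
                   pctSharedNegative = "numeric",
                   pctSharedPositive = "numeric",
                   sameDirection = "integer",
                   oppositeDirection = "integer",
                   perChromosome = "data.frame"))

setValidity("GroupComparison", function(object) {
    msg <- character()
    if (object@sharedNegative > min(object@nNegativeA, object@nNegativeB))
        msg <- c(msg, "sharedNegative exceeds a group's negative count")
    if (object@sharedPositive > min(object@nPositiveA, object@nPositiveB))
        msg <- c(msg, "sharedPositive exceeds a group's positive count")
    if (object@sameDirection != object@sharedNegative + object@sharedPositive)
        msg <- c(msg, "sameDirection must equal sharedNegative + sharedPositive")
    if (length(msg)) msg else TRUE
})

#' SimConfig: scenario definition for the synthetic-data generator
#'
#' Defines a simulated cohort of \code{nFemales + nMales} diploid
#' individuals genotyped at \code{nLoci} biallelic SNPs under
#' Hardy-Weinberg proportions, with per-cell missingness, negative-binomial
#' read depths, binomial heterozygote read splits, an optional fraction of
#' paralog-like loci (inflated heterozygosity and skewed read ratios), and
#' \code{nPairs} observed mate pairs drawn with per-locus assortment
#' injected at \code{assortLoci}.
#'
#' @slot nLoci,nFemales,nMales,nPairs scenario sizes.
#' @slot mafMin,mafMax minor-allele frequencies drawn uniformly in this
#'   range (defaults 0.05, 0.5).
#' @slot missingRate per-cell probability a genotype is missing.
#' @slot depthMean,depthDispersion negative-binomial read-depth model
#'   (mean and size).
#' @slot paralogFraction fraction of loci simulated as paralog-like.
#' @slot assortLoci data.frame with columns \code{locus} (index),
#'   \code{direction} (\code{"negative"} or \code{"positive"}) and
#'   \code{beta} (strength, >= 0); zero rows means random mating.
#' @slot groupLabel label attached to the simulated MatePairSet.
#' @slot nChromosomes loci are spread round-robin over this many chromosomes.
#' @slot seed integer RNG seed; identical config + seed gives identical output.
#' @seealso [SimConfig()], [simulateCohort()], [simulatePairs()]
#' @export
setClass("SimConfig",
    representation(nLoci = "integer",
                   nFemales = "integer",
                   nMales = "integer",
                   nPairs = "integer",
                   mafMin = "numeric",
                   mafMax = "numeric",
                   missingRate = "numeric",
                   depthMean = "numeric",
                   depthDispersion = "numeric",
                   paralogFraction = "numeric",
                   assortLoci = "data.frame",
                   groupLabel = "character",
                   nChromosomes = "integer",
                   seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (!(object@mafMin > 0 && object@mafMin <= object@mafMax &&
          object@mafMax <= 0.5))
        msg <- c(msg, "need 0 < mafMin <= mafMax <= 0.5")
    if (object@missingRate < 0 || object@missingRate >= 1)
        msg <- c(msg, "missingRate must lie in [0, 1)")
    if (object@nPairs > object@nFemales * object@nMales)
        msg <- c(msg, "nPairs cannot exceed nFemales * nMales unique pairs")
    al <- object@assortLoci
    if (nrow(al)) {
        if (!all(c("locus", "direction", "beta") %in% colnames(al)))
            msg <- c(msg, "assortLoci needs columns locus, direction, beta")
        else {
            if (any(al$locus < 1 | al$locus > object@nLoci))
                msg <- c(msg, "assortLoci$locus out of range")
            if (!all(al$direction %in% c("negative", "positive")))
                msg <- c(msg, "assortLoci$direction must be negative/positive")
            if (any(!is.finite(al$beta)) || any(al$beta < 0))
                msg <- c(msg, "assortLoci$beta must be finite and >= 0")
        }
    }
    if (length(msg)) msg else TRUE
})
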