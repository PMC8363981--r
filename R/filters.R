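#' Remove individuals with excess missing genotypes
#'
#' Drops every individual whose fraction of missing genotype cells strictly
#' exceeds \code{maxMissing} ("more than" semantics: exactly at the
#' threshold is retained). Survivor order is preserved.
#'
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @param maxMissing missing fraction threshold (default 0.20).
#' @return a list with \code{ge} (the filtered object) and \code{removed}
#'   (character ids of dropped individuals).
#' @export
filterIndividuals <- function(ge, maxMissing = 0.20) {
    if (nrow(ge) == 0L)
        return(list(ge = ge, removed = character()))
    frac <- colMeans(is.na(dosage(ge)))
    drop <- frac > maxMissing
    if (all(drop))
        stop("all individuals exceed the missingness threshold")
    list(ge = ge[, !drop], removed = colnames(ge)[drop])
}

# Per-site mean total read depth. depthMissing = "exclude" averages over
# individuals with a non-missing genotype only; "zero" averages over all
# individuals, counting absent depth as 0.
siteMeanDepth <- function(ge, depthMissing = "exclude") {
    if (!hasDepths(ge))
        stop("allele depths are absent; skip the depth filter explicitly ",
             "(set minMeanDepth = NA and maxMeanDepth = NA)")
    ad <- alleleDepths(ge)
    tot <- ifelse(is.na(ad$ref), 0L, ad$ref) +
           ifelse(is.na(ad$alt), 0L, ad$alt)
    if (depthMissing == "exclude") {
        keep <- !is.na(dosage(ge))
        n <- rowSums(keep)
        s <- rowSums(tot * keep)
        ifelse(n > 0, s / n, 0)
    } else {
        rowMeans(tot)
    }
}

#' Remove sites by mean read depth
#'
#' A site is removed when its mean total depth over individuals is strictly
#' below \code{minMeanDepth} or strictly above \code{maxMeanDepth}
#' ("less than"/"exceeded" semantics).
#'
#' @inheritParams filterIndividuals
#' @param minMeanDepth,maxMeanDepth depth bounds (defaults 5 and 30); NA
#'   disables a bound.
#' @param depthMissing see [FilterConfig()].
#' @return a list with \code{ge} and \code{removed} (locus ids).
#' @export
filterSitesByDepth <- function(ge, minMeanDepth = 5, maxMeanDepth = 30,
                               depthMissing = "exclude") {
    md <- siteMeanDepth(ge, depthMissing)
    drop <- rep(FALSE, nrow(ge))
    if (!is.na(minMeanDepth)) drop <- drop | md < minMeanDepth
    if (!is.na(maxMeanDepth)) drop <- drop | md > maxMeanDepth
    list(ge = ge[!drop, ], removed = rownames(ge)[drop])
}

#' Remove sites with excess missing data
#'
#' A site is removed when its fraction of missing genotypes strictly
#' exceeds \code{maxMissing}.
#'
#' @inheritParams filterIndividuals
#' @param maxMissing missing fraction threshold (default 0.80).
#' @return a list with \code{ge} and \code{removed} (locus ids).
#' @export
filterSitesByMissingness <- function(ge, maxMissing = 0.80) {
    drop <- rowMeans(is.na(dosage(ge))) > maxMissing
    list(ge = ge[!drop, ], removed = rownames(ge)[drop])
}

#' HDplot statistics per locus
#'
#' For each locus computes H, the fraction of genotyped individuals called
#' heterozygous, and the read-ratio deviation
#' \eqn{D = (a - b) / \sqrt{a + b}}, where \eqn{a} and \eqn{b} are the ref-
#' and alt-allele read counts summed over heterozygous individuals at that
#' locus. In a well-behaved diploid SNP heterozygote reads split ~50/50 and
#' D stays near 0; collapsed paralogs show excess heterozygosity and/or a
#' skewed pooled read ratio. Loci with zero heterozygotes get D = 0 and are
#' judged on H alone.
#'
#' @inheritParams filterIndividuals
#' @return a data.frame with columns \code{locus_id}, \code{chrom},
#'   \code{pos}, \code{H}, \code{D}, \code{nHet}.
#' @export
hdplotStats <- function(ge) {
    if (!hasDepths(ge))
        stop("allele depths are required for HDplot paralog detection")
    d <- dosage(ge)
    het <- !is.na(d) & d == 1L
    nGeno <- rowSums(!is.na(d))
    H <- ifelse(nGeno > 0, rowSums(het) / nGeno, 0)
    ad <- alleleDepths(ge)
    a <- rowSums(ifelse(het & !is.na(ad$ref), ad$ref, 0L))
    b <- rowSums(ifelse(het & !is.na(ad$alt), ad$alt, 0L))
    D <- ifelse(a + b > 0, (a - b) / sqrt(a + b), 0)
    data.frame(locus_id = rownames(ge),
               chrom = as.character(GenomeInfoDb::seqnames(rowRanges(ge))),
               pos = BiocGenerics::start(rowRanges(ge)),
               H = H, D = D, nHet = rowSums(het),
               stringsAsFactors = FALSE)
}

#' HDplot-style paralog blacklist
#'
#' Flags a locus as a putative paralog when H strictly exceeds
#' \code{hdMaxHeterozygosity} or D falls strictly outside
#' \code{[hdMinD, hdMaxD]}. The asymmetric default D window (-5, 7) follows
#' the convention of tuning the read-ratio z-score bounds separately per
#' tail.
#'
#' @inheritParams filterIndividuals
#' @param hdMaxHeterozygosity,hdMinD,hdMaxD thresholds; see
#'   [FilterConfig()].
#' @return a data.frame (subset of [hdplotStats()] rows) listing
#'   blacklisted loci.
#' @export
hdplotParalogs <- function(ge, hdMaxHeterozygosity = 0.6, hdMinD = -5,
                           hdMaxD = 7) {
    st <- hdplotStats(ge)
    bad <- st$H > hdMaxHeterozygosity | st$D < hdMinD | st$D > hdMaxD
    st[bad, , drop = FALSE]
}

#' Write a locus blacklist
#'
#' Two-column TSV (chromosome, position) usable as an exclusion list.
#'
#' @param blacklist data.frame with \code{chrom} and \code{pos} columns,
#'   e.g. from [hdplotParalogs()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBlacklist <- function(blacklist, path) {
    write.table(blacklist[, c("chrom", "pos")], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Run the full post-calling filter chain
#'
#' Applies, in order: (1) HDplot paralog blacklisting, (2) individual-level
#' missingness, (3) mean site depth, (4) site-level missingness. A site
#' removed by an earlier stage is never re-counted by a later one, so the
#' report satisfies \code{nSitesOut = nSitesIn - sum(stage removals)}.
#' Stages whose thresholds are \code{NA} are skipped; the depth and paralog
#' stages are also skipped (with a message) when the object carries no
#' allele depths. After individual removal the minor allele is re-derived
#' from the surviving cohort. The chain is idempotent: re-running it on its
#' own output removes nothing.
#'
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @param config a \linkS4class{FilterConfig}.
#' @param verbose log one line per stage.
#' @return a list with \code{ge} (filtered, re-encoded) and \code{report}
#'   (a \linkS4class{FilterReport}).
#' @export
runFilterChain <- function(ge, config = FilterConfig(), verbose = FALSE) {
    nIn <- nrow(ge)
    nPar <- nDep <- nMis <- 0L
    removedInd <- character()

    hdOn <- !is.na(config@hdMaxHeterozygosity) && hasDepths(ge)
    if (hdOn) {
        bl <- hdplotParalogs(ge, config@hdMaxHeterozygosity,
                             config@hdMinD, config@hdMaxD)
        nPar <- nrow(bl)
        ge <- ge[!rownames(ge) %in% bl$locus_id, ]
        .msg(verbose, "paralog blacklist: removed ", nPar, " site(s)")
    } else .msg(verbose, "paralog blacklist: skipped")

    if (!is.na(config@maxIndividualMissing)) {
        fi <- filterIndividuals(ge, config@maxIndividualMissing)
        ge <- fi$ge; removedInd <- fi$removed
        if (length(removedInd)) ge <- encodeMinorAllele(ge)
        .msg(verbose, "individual missingness: removed ",
             length(removedInd), " individual(s)")
    }

    if (!is.na(config@minMeanDepth) || !is.na(config@maxMeanDepth)) {
        if (hasDepths(ge)) {
            fd <- filterSitesByDepth(ge, config@minMeanDepth,
                                     config@maxMeanDepth,
                                     config@depthMissing)
            ge <- fd$ge; nDep <- length(fd$removed)
            .msg(verbose, "site depth: removed ", nDep, " site(s)")
        } else .msg(verbose, "site depth: skipped (no allele depths)")
    }

    if (!is.na(config@maxSiteMissing)) {
        fm <- filterSitesByMissingness(ge, config@maxSiteMissing)
        ge <- fm$ge; nMis <- length(fm$removed)
        .msg(verbose, "site missingness: removed ", nMis, " site(s)")
    }

    if (nrow(ge) == 0L)
        warning("no sites survive the filter chain")
    report <- FilterReport(nSitesIn = nIn,
                           nIndividualsRemoved = length(removedInd),
                           nSitesRemovedParalog = nPar,
                           nSitesRemovedDepth = nDep,
                           nSitesRemovedMissing = nMis,
                           removedIndividuals = removedInd)
    list(ge = ge, report = report)
}
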