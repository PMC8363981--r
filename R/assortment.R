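#' Shared-allele score of a mate pair at one locus
#'
#' Given the two mates' minor-allele dosages, returns how many allele
#' classes the genotypes share: 2 when the genotypes are identical (e.g.
#' AA with AA, or Aa with Aa), 1 when they share one allele class (e.g. Aa
#' with AA), and 0 when they share none (AA with aa). This equals
#' \code{2 - |d1 - d2|}, and is \code{NA} when either genotype is missing.
#' The score is symmetric in its arguments and invariant under relabelling
#' the minor allele (\code{d -> 2 - d} applied to both mates).
#'
#' @param dFemale,dMale dosage vectors with values 0, 1, 2 or \code{NA}.
#' @return integer vector of scores in \{0, 1, 2\} or \code{NA}.
#' @export
#' @examples
#' sharedAlleles(c(0, 1, 0), c(2, 1, 1)) # 0 2 1
sharedAlleles <- function(dFemale, dMale) {
    ok <- function(d) all(is.na(d) | d %in% .VALID_DOSAGE)
    if (!ok(dFemale) || !ok(dMale))
        stop("dosages must be 0, 1, 2 or NA")
    as.integer(2L - abs(dFemale - dMale))
}

#' Observed mean sharing at a locus
#'
#' Mean shared-allele score over the pairs where \emph{both} members are
#' genotyped at the locus. Because not every individual is genotyped at
#' every SNP, the effective pair count varies by locus and is reported.
#'
#' @param pairs a \linkS4class{MatePairSet}.
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @param locus locus id (rowname) or row index.
#' @return list with \code{mean} (NA when no informative pairs) and
#'   \code{nPairsUsed}.
#' @export
observedMeanSharing <- function(pairs, ge, locus) {
    k <- resolveLocus(ge, locus)
    d <- dosage(ge)
    s <- sharedAlleles(d[k, match(females(pairs), colnames(ge))],
                       d[k, match(males(pairs), colnames(ge))])
    n <- sum(!is.na(s))
    list(mean = if (n > 0) mean(s, na.rm = TRUE) else NA_real_,
         nPairsUsed = n)
}

resolveLocus <- function(ge, locus) {
    k <- if (is.character(locus)) match(locus, rownames(ge))
         else as.integer(locus)
    if (is.na(k) || k < 1L || k > nrow(ge))
        stop("locus not found: ", locus)
    k
}

.SHARE_TABLE <- outer(0:2, 0:2, function(a, b) 2 - abs(a - b))

# Null replicate means under the default permute-males scheme: each
# replicate randomly re-matches the multiset of males in the pair set
# bijectively to the females (a classical permutation of observed mates)
# and averages the sharing score over assignments where both members are
# genotyped. Only the dosage-class cross-tabulation of a matching matters,
# and under a uniform random bijection that 4x4 table (classes 0/1/2/
# missing on both sides, margins fixed at the observed class counts) is
# multivariate hypergeometric - drawn directly with r2dtable (Patefield),
# avoiding a per-assignment loop. Replicates with fewer informative
# assignments than minPairs are redrawn (counted, capped at 50 rounds;
# stragglers stay NA).
nullPermuteMeans <- function(fDos, mDos, nPerm, minPairs = 2L) {
    cF <- as.integer(dosageCounts(fDos))
    cM <- as.integer(dosageCounts(mDos))
    if (sum(cF[1:3]) == 0L || sum(cM[1:3]) == 0L) {
        out <- rep(NA_real_, nPerm)
        attr(out, "nRedrawn") <- 0L
        return(out)
    }
    draw <- function(n) {
        vapply(stats::r2dtable(n, cF, cM), function(tt) {
            inf <- tt[1:3, 1:3]
            V <- sum(inf)
            if (V >= minPairs) sum(inf * .SHARE_TABLE) / V else NA_real_
        }, numeric(1))
    }
    means <- draw(nPerm)
    nRedrawn <- 0L
    rounds <- 0L
    while (anyNA(means) && rounds < 50L) {
        idx <- which(is.na(means))
        nRedrawn <- nRedrawn + length(idx)
        means[idx] <- draw(length(idx))
        rounds <- rounds + 1L
    }
    attr(means, "nRedrawn") <- nRedrawn
    means
}

# Null replicate means under the resample-males scheme: every female is
# assigned a male drawn with replacement from the male multiset. Each
# replicate's score total decomposes into three multinomial draws (one per
# female dosage class over the four male classes 0/1/2/missing). Note this
# null carries male-composition variance that the observed statistic does
# not, making it conservative relative to permute-males; it is kept as the
# literal reading of assigning each female a random male from the dataset.
nullReplicateMeans <- function(fDos, mDos, nPerm, minPairs = 2L) {
    mCnt <- dosageCounts(mDos)
    cF <- dosageCounts(fDos)[1:3]
    if (sum(mCnt) == 0L || sum(cF) == 0L) {
        out <- rep(NA_real_, nPerm)
        attr(out, "nRedrawn") <- 0L
        return(out)
    }
    p <- mCnt / sum(mCnt)
    draw <- function(n) {
        S <- numeric(n); V <- numeric(n)
        for (dd in 0:2) {
            cd <- cF[[dd + 1L]]
            if (cd == 0) next
            cnt <- rmultinom(n, cd, p)[1:3, , drop = FALSE]
            S <- S + colSums(cnt * (2 - abs(dd - 0:2)))
            V <- V + colSums(cnt)
        }
        ifelse(V >= minPairs, S / V, NA_real_)
    }
    means <- draw(nPerm)
    nRedrawn <- 0L
    rounds <- 0L
    while (anyNA(means) && rounds < 50L) {
        idx <- which(is.na(means))
        nRedrawn <- nRedrawn + length(idx)
        means[idx] <- draw(length(idx))
        rounds <- rounds + 1L
    }
    attr(means, "nRedrawn") <- nRedrawn
    means
}

# Null distribution of single random pair scores (sensitivity scheme):
# nPerm single (female, male) draws, each scored once.
nullSinglePairScores <- function(fDos, mDos, nPerm) {
    if (all(is.na(fDos)) || all(is.na(mDos)))
        return(rep(NA_real_, nPerm))
    f <- sample(fDos, nPerm, replace = TRUE)
    m <- sample(mDos, nPerm, replace = TRUE)
    as.numeric(2L - abs(f - m))
}

#' Permutation null for one locus
#'
#' Builds the null distribution of mean sharing under random mating by
#' randomly re-matching, in each of \code{nPermutations} replicates, the
#' multiset of males appearing in the pair set to the females (genotypes
#' are held fixed; only the pairing is randomised). Replicate means are computed under the
#' same both-members-genotyped rule as the observed mean. With
#' \code{nullScheme = "single-pairs"} the null is instead the distribution
#' of single random pair scores. The RNG stream is derived from
#' \code{(config seed, locus index)}, so per-locus results do not depend on
#' processing order.
#'
#' @param pairs a \linkS4class{MatePairSet}.
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @param locus locus id or row index.
#' @param config an \linkS4class{AssortConfig}.
#' @return numeric vector of \code{nPermutations} replicate means (values
#'   in [0, 2]; \code{NA} for replicates that could not reach
#'   \code{minPairsPerLocus} informative assignments), with attribute
#'   \code{"nRedrawn"}.
#' @export
permutationNull <- function(pairs, ge, locus, config = AssortConfig()) {
    k <- resolveLocus(ge, locus)
    if (length(unique(males(pairs))) < 2L)
        stop("need at least 2 distinct males in the pair set")
    d <- dosage(ge)
    fDos <- d[k, match(females(pairs), colnames(ge))]
    mDos <- d[k, match(males(pairs), colnames(ge))]
    set.seed(deriveSeed(config@seed, k))
    switch(config@nullScheme,
        "permute-males" = nullPermuteMeans(fDos, mDos,
            config@nPermutations, config@minPairsPerLocus),
        "resample-males" = nullReplicateMeans(fDos, mDos,
            config@nPermutations, config@minPairsPerLocus),
        "single-pairs" = nullSinglePairScores(fDos, mDos,
            config@nPermutations))
}

#' Percentile of the observed mean in the null
#'
#' Mid-rank convention: (number of null values strictly below the observed
#' mean plus half the number exactly equal) divided by the number of null
#' values. Ties therefore contribute symmetrically and a degenerate null
#' (all replicates equal to the observed mean, e.g. a locus where every
#' individual is heterozygous) yields exactly 0.5.
#'
#' @param observed observed mean sharing.
#' @param null numeric vector of null replicate values (NAs are dropped).
#' @return percentile in [0, 1], or NA for an empty null.
#' @export
percentileOfObserved <- function(observed, null) {
    null <- null[!is.na(null)]
    n <- length(null)
    if (n == 0L || is.na(observed)) return(NA_real_)
    eps <- 1e-9
    (sum(null < observed - eps) +
     0.5 * sum(abs(null - observed) <= eps)) / n
}

#' Classify a locus from its null percentile
#'
#' \code{"negative"} (disassortative: mates less similar than random) when
#' the percentile is strictly below the lower cutoff, \code{"positive"}
#' (assortative) strictly above the upper cutoff, else \code{"none"}.
#' Values exactly at a cutoff are \code{"none"}.
#'
#' @param percentile numeric vector of percentiles in [0, 1].
#' @param config an \linkS4class{AssortConfig}.
#' @return character vector over \{"negative", "positive", "none"\} with NA
#'   preserved.
#' @export
classifyLocus <- function(percentile, config = AssortConfig()) {
    out <- rep(NA_character_, length(percentile))
    ok <- !is.na(percentile)
    out[ok] <- "none"
    out[ok & percentile < config@lowerCutoff] <- "negative"
    out[ok & percentile > config@upperCutoff] <- "positive"
    out
}

#' Per-locus assortment scan over one mating group
#'
#' For every locus in the object: computes the observed mean sharing over
#' the group's pairs, builds the permutation null, locates the observed
#' mean's percentile in it, and classifies the locus. Loci with fewer than
#' \code{minPairsPerLocus} informative pairs are emitted with
#' classification \code{"none"} and \code{low_n = TRUE} rather than being
#' dropped, so two groups' scans stay aligned on the same locus universe.
#'
#' @param pairs a \linkS4class{MatePairSet}.
#' @param ge a \linkS4class{GenotypeExperiment} (already filtered).
#' @param config an \linkS4class{AssortConfig}.
#' @return a \code{DataFrame}, one row per locus, with columns
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{locus_id},
#'   \code{n_pairs_used}, \code{observed_mean}, \code{null_mean},
#'   \code{null_sd}, \code{percentile}, \code{classification},
#'   \code{low_n}; the config and group label are stored in
#'   \code{metadata()}.
#' @export
runGroupAssortment <- function(pairs, ge, config = AssortConfig()) {
    if (length(pairs) == 0L) stop("pair set is empty")
    validatePairs(pairs, ge)
    d <- dosage(ge)
    fIdx <- match(females(pairs), colnames(ge))
    mIdx <- match(males(pairs), colnames(ge))
    L <- nrow(ge)
    obs <- nUsed <- nullMean <- nullSd <- pct <- rep(NA_real_, L)
    cls <- rep("none", L)
    lowN <- rep(FALSE, L)
    for (k in seq_len(L)) {
        fDos <- d[k, fIdx]
        mDos <- d[k, mIdx]
        s <- 2L - abs(fDos - mDos)
        n <- sum(!is.na(s))
        nUsed[k] <- n
        if (n < config@minPairsPerLocus) {
            lowN[k] <- TRUE
            next
        }
        obs[k] <- sum(s, na.rm = TRUE) / n
        set.seed(deriveSeed(config@seed, k))
        null <- switch(config@nullScheme,
            "permute-males" = nullPermuteMeans(fDos, mDos,
                config@nPermutations, config@minPairsPerLocus),
            "resample-males" = nullReplicateMeans(fDos, mDos,
                config@nPermutations, config@minPairsPerLocus),
            "single-pairs" = nullSinglePairScores(fDos, mDos,
                config@nPermutations))
        nullMean[k] <- mean(null, na.rm = TRUE)
        nullSd[k] <- sd(null, na.rm = TRUE)
        pct[k] <- percentileOfObserved(obs[k], null)
        cc <- classifyLocus(pct[k], config)
        cls[k] <- if (is.na(cc)) "none" else cc
        if (config@verbose && k %% 1000L == 0L)
            message("processed ", k, "/", L, " loci")
    }
    rr <- rowRanges(ge)
    out <- DataFrame(
        chrom = as.character(GenomeInfoDb::seqnames(rr)),
        pos = BiocGenerics::start(rr),
        ref = rowData(ge)$ref, alt = rowData(ge)$alt,
        locus_id = rownames(ge),
        n_pairs_used = as.integer(nUsed),
        observed_mean = obs, null_mean = nullMean, null_sd = nullSd,
        percentile = pct, classification = cls, low_n = lowN)
    metadata(out) <- list(group = groupLabel(pairs),
                          n_pairs = length(pairs),
                          n_permutations = config@nPermutations,
                          lower_cutoff = config@lowerCutoff,
                          upper_cutoff = config@upperCutoff,
                          null_scheme = config@nullScheme,
                          seed = config@seed)
    out
}
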