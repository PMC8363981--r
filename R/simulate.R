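#' Simulate a genotyped cohort
#'
#' Draws, per locus, a minor-allele frequency \eqn{q} uniform on
#' [\code{mafMin}, \code{mafMax}] and genotypes under Hardy-Weinberg
#' proportions (dosage 2 with probability \eqn{q^2}, 1 with
#' \eqn{2q(1-q)}, 0 with \eqn{(1-q)^2}). Per-cell total read depth is
#' negative binomial (mean \code{depthMean}, size
#' \code{depthDispersion}); heterozygote reads split Binomial(depth, 0.5)
#' between the two alleles, homozygotes put all reads on their allele.
#' A \code{paralogFraction} of loci is simulated paralog-like: inflated
#' heterozygosity (het probability 0.75 regardless of \eqn{q}) and a
#' skewed heterozygote read split (Binomial(depth, 0.85) toward ref), the
#' signature the HDplot filter is designed to catch. Genotypes are then
#' masked missing with probability \code{missingRate}; masked cells get
#' zero read depth, as an uncalled genotype would. Females are listed
#' first (\code{F001...}), then males (\code{M001...}); loci are spread
#' round-robin over \code{nChromosomes} chromosomes.
#'
#' Identical config (including seed) gives bit-identical output.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{GenotypeExperiment} with allele depths; row
#'   metadata records \code{simulatedMaf} (the generating \eqn{q}) and
#'   \code{simulatedParalog}.
#' @export
#' @examples
#' ge <- simulateCohort(SimConfig(nLoci = 20, nFemales = 5, nMales = 5,
#'                                nPairs = 5, seed = 42))
#' ge
simulateCohort <- function(config = SimConfig()) {
    validObject(config)
    set.seed(deriveSeed(config@seed, 0L))
    L <- config@nLoci
    nInd <- config@nFemales + config@nMales
    q <- runif(L, config@mafMin, config@mafMax)
    isParalog <- rep(FALSE, L)
    nPar <- round(config@paralogFraction * L)
    if (nPar > 0) isParalog[sample.int(L, nPar)] <- TRUE

    d <- matrix(NA_integer_, L, nInd)
    for (k in seq_len(L)) {
        if (isParalog[k]) {
            # collapsed-duplicate signature: excess heterozygosity
            pr <- c(0.125, 0.75, 0.125)
        } else {
            pr <- c((1 - q[k])^2, 2 * q[k] * (1 - q[k]), q[k]^2)
        }
        d[k, ] <- sample(0:2, nInd, replace = TRUE, prob = pr)
    }
    depth <- matrix(rnbinom(L * nInd, mu = config@depthMean,
                            size = config@depthDispersion), L, nInd)
    hetSplit <- ifelse(isParalog, 0.85, 0.5)
    altReads <- matrix(0L, L, nInd)
    het <- d == 1L
    # ref-allele read count for heterozygotes; homozygote alt takes all.
    # depth[het] enumerates cells column-major; hetSplitPerCell matches.
    refHet <- rbinom(sum(het), depth[het], hetSplitPerCell(het, hetSplit))
    altReads[het] <- depth[het] - refHet
    altReads[d == 2L] <- depth[d == 2L]
    refReads <- depth - altReads
    if (config@missingRate > 0) {
        miss <- matrix(runif(L * nInd) < config@missingRate, L, nInd)
        d[miss] <- NA_integer_
        refReads[miss] <- 0L
        altReads[miss] <- 0L
    }
    ids <- c(sprintf("F%03d", seq_len(config@nFemales)),
             sprintf("M%03d", seq_len(config@nMales)))
    colnames(d) <- ids
    chrom <- paste0("chr", ((seq_len(L) - 1L) %% config@nChromosomes) + 1L)
    pos <- 1000L * (((seq_len(L) - 1L) %/% config@nChromosomes) + 1L)
    ge <- GenotypeExperiment(d, chrom = chrom, pos = pos,
        ref = rep("A", L), alt = rep("C", L),
        sex = rep(c("female", "male"),
                  c(config@nFemales, config@nMales)),
        origin = rep(config@groupLabel, nInd),
        refDepth = refReads, altDepth = altReads)
    rowData(ge)$simulatedMaf <- q
    rowData(ge)$simulatedParalog <- isParalog
    ge
}

# Per-locus heterozygote read-split probability expanded to one value per
# TRUE cell of `het`, in the same column-major order logical subsetting
# uses.
hetSplitPerCell <- function(het, hetSplit) {
    idx <- which(het, arr.ind = TRUE)
    hetSplit[idx[, 1L]]
}

#' Simulate observed mate pairs with per-locus assortment
#'
#' Draws \code{nPairs} unique (female, male) pairs from the cohort with
#' probability proportional to
#' \eqn{\prod_l w_l^{s_l}}, the product running over the configured
#' assorting loci, where \eqn{s_l} is the pair's shared-allele score at
#' locus \eqn{l} and \eqn{w_l = e^{-\beta}} for negative direction (pairs
#' sharing fewer alleles favoured) or \eqn{e^{+\beta}} for positive.
#' A missing genotype contributes factor 1. With no assorting loci (or all
#' \eqn{\beta = 0}) every pair has equal weight and mating is uniformly
#' random. Sampling is exact categorical sampling without replacement over
#' the enumerable female-by-male table, so arbitrarily strong biases pose
#' no acceptance-rate problem.
#'
#' @param ge a \linkS4class{GenotypeExperiment} from [simulateCohort()]
#'   (any cohort with female/male sexes works).
#' @param config the \linkS4class{SimConfig} (uses \code{nPairs},
#'   \code{assortLoci}, \code{groupLabel}, \code{seed}).
#' @return a \linkS4class{MatePairSet}.
#' @export
simulatePairs <- function(ge, config = SimConfig()) {
    validObject(config)
    sex <- colData(ge)$sex
    fem <- colnames(ge)[!is.na(sex) & sex == "female"]
    mal <- colnames(ge)[!is.na(sex) & sex == "male"]
    if (config@nPairs > length(fem) * length(mal))
        stop("nPairs exceeds the number of distinct female x male pairs")
    logW <- matrix(0, length(fem), length(mal))
    al <- config@assortLoci
    if (nrow(al)) {
        d <- dosage(ge)
        for (i in seq_len(nrow(al))) {
            k <- al$locus[i]
            beta <- al$beta[i] *
                if (al$direction[i] == "negative") -1 else 1
            s <- outer(d[k, fem], d[k, mal],
                       function(a, b) 2 - abs(a - b))
            s[is.na(s)] <- 0  # missing genotype contributes factor 1
            logW <- logW + beta * s
        }
    }
    w <- exp(logW - max(logW))
    if (sum(w > 0) < config@nPairs)
        stop("fewer than nPairs pairs have positive weight; ",
             "reduce beta or nPairs")
    set.seed(deriveSeed(config@seed, 1L))
    pick <- sample.int(length(w), config@nPairs, replace = FALSE,
                       prob = as.vector(w))
    fi <- ((pick - 1L) %% length(fem)) + 1L
    mi <- ((pick - 1L) %/% length(fem)) + 1L
    MatePairSet(fem[fi], mal[mi], groupLabel = config@groupLabel,
                cohort = ge)
}

#' Simulate a complete one-group study
#'
#' Convenience wrapper: [simulateCohort()] then [simulatePairs()].
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with \code{ge} and \code{pairs}.
#' @export
simulateStudy <- function(config = SimConfig()) {
    ge <- simulateCohort(config)
    list(ge = ge, pairs = simulatePairs(ge, config))
}
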