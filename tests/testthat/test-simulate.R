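test_that("genotypes follow Hardy-Weinberg expectations at q = 0.5", {
    cfg <- SimConfig(nLoci = 200, nFemales = 100, nMales = 100,
                     nPairs = 100, mafMin = 0.5, mafMax = 0.5,
                     missingRate = 0, seed = 77)
    ge <- simulateCohort(cfg)
    d <- dosage(ge)
    # undo the minor-allele flip: alt dosage ~ Binomial(2, 0.5) per cell
    flip <- !rowData(ge)$minorIsAlt
    d[flip, ] <- 2L - d[flip, , drop = FALSE]
    n <- length(d)
    se <- sqrt(0.5 / n)
    expect_lt(abs(mean(d) - 1), 3 * se)
    expect_false(anyNA(d))
})

test_that("missingness is applied at the configured rate", {
    cfg <- SimConfig(nLoci = 100, nFemales = 50, nMales = 50,
                     nPairs = 50, missingRate = 0.1, seed = 4)
    d <- dosage(simulateCohort(cfg))
    rate <- mean(is.na(d))
    se <- sqrt(0.1 * 0.9 / length(d))
    expect_lt(abs(rate - 0.1), 4 * se)
    # missing cells carry zero read depth
    ge <- simulateCohort(cfg)
    ad <- alleleDepths(ge)
    miss <- is.na(dosage(ge))
    expect_true(all(ad$ref[miss] == 0L & ad$alt[miss] == 0L))
})

test_that("a clean simulation yields no paralog flags; injected ones do", {
    clean <- simulateCohort(SimConfig(nLoci = 500, nFemales = 150,
                                      nMales = 150, nPairs = 150,
                                      paralogFraction = 0, seed = 101))
    expect_equal(nrow(hdplotParalogs(clean)), 0L)

    dirty <- simulateCohort(SimConfig(nLoci = 300, nFemales = 150,
                                      nMales = 150, nPairs = 150,
                                      paralogFraction = 0.1, seed = 102))
    marked <- rownames(dirty)[rowData(dirty)$simulatedParalog]
    flagged <- hdplotParalogs(dirty)$locus_id
    expect_gte(mean(marked %in% flagged), 0.9)
    # false flags on clean loci stay rare
    cleanLoci <- setdiff(rownames(dirty), marked)
    expect_lte(mean(cleanLoci %in% flagged), 0.02)
})

test_that("identical config and seed give bit-identical output", {
    cfg <- SimConfig(nLoci = 50, nFemales = 20, nMales = 20, nPairs = 30,
                     missingRate = 0.05, paralogFraction = 0.05,
                     seed = 55)
    s1 <- simulateStudy(cfg)
    s2 <- simulateStudy(cfg)
    expect_identical(dosage(s1$ge), dosage(s2$ge))
    expect_identical(alleleDepths(s1$ge), alleleDepths(s2$ge))
    expect_identical(females(s1$pairs), females(s2$pairs))
    expect_identical(males(s1$pairs), males(s2$pairs))
})

test_that("with no assorting loci pair sampling is uniform", {
    # 3 x 3 grid, single pair per draw, frequencies over many draws
    counts <- matrix(0, 3, 3)
    base <- SimConfig(nLoci = 5, nFemales = 3, nMales = 3, nPairs = 1)
    for (s in 1:900) {
        cfg <- SimConfig(nLoci = 5, nFemales = 3, nMales = 3, nPairs = 1,
                         seed = 2000 + s)
        ge <- simulateCohort(base)   # genotypes irrelevant, reuse layout
        p <- simulatePairs(ge, cfg)
        fi <- as.integer(sub("F0*", "", females(p)))
        mi <- as.integer(sub("M0*", "", males(p)))
        counts[fi, mi] <- counts[fi, mi] + 1
    }
    chi <- sum((counts - 100)^2 / 100)
    # chi-square with 8 df; far-tail bound
    expect_lt(chi, qchisq(1 - 1e-5, df = 8))
})

test_that("injected assortment shifts sharing in the stated direction", {
    dirs <- c("negative", "positive")
    for (dir in dirs) {
        diffs <- numeric(10)
        for (r in 1:10) {
            cfg <- SimConfig(nLoci = 30, nFemales = 40, nMales = 40,
                             nPairs = 60, seed = 300 + r,
                             assortLoci = data.frame(locus = 1L,
                                                     direction = dir,
                                                     beta = 2))
            sim <- simulateStudy(cfg)
            obs <- observedMeanSharing(sim$pairs, sim$ge, 1)$mean
            # random-pairing expectation from the same male multiset
            null <- permutationNull(sim$pairs, sim$ge, 1,
                                    AssortConfig(nPermutations = 400,
                                                 seed = 400 + r))
            diffs[r] <- obs - mean(null, na.rm = TRUE)
        }
        if (dir == "negative") expect_lt(mean(diffs), 0)
        else expect_gt(mean(diffs), 0)
        # sign consistent in at least 9 of 10 replicates
        expect_gte(sum(if (dir == "negative") diffs < 0 else diffs > 0),
                   9)
    }
})

test_that("overly constrained scenarios are rejected", {
    expect_error(SimConfig(nFemales = 3, nMales = 3, nPairs = 10),
                 "nPairs")
    expect_error(SimConfig(nLoci = 10, assortLoci = data.frame(
        locus = 99L, direction = "negative", beta = 1)), "out of range")
    expect_error(SimConfig(mafMin = 0, mafMax = 0.5), "mafMin")
})
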