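test_that("sharing score matches the allele-class oracle on all 9 combos", {
    for (d1 in 0:2) for (d2 in 0:2) {
        expect_identical(sharedAlleles(d1, d2),
                         as.integer(sharingOracle(d1, d2)),
                         info = paste(d1, d2))
        # symmetry and relabeling invariance, exhaustively
        expect_identical(sharedAlleles(d1, d2), sharedAlleles(d2, d1))
        expect_identical(sharedAlleles(d1, d2),
                         sharedAlleles(2L - d1, 2L - d2))
    }
    expect_identical(sharedAlleles(c(0, NA, 1), c(2, 1, NA)),
                     c(0L, NA, NA))
    expect_error(sharedAlleles(3, 0), "dosages")
})

test_that("observed mean uses only pairs with both members genotyped", {
    d <- rbind(c(0L, 1L, 1L, 0L, 2L, 2L),
               c(NA, 1L, 1L, 0L, 1L, NA),
               c(NA, NA, NA, 0L, 1L, NA))
    colnames(d) <- c("F1", "F2", "F3", "M1", "M2", "M3")
    ge <- toyGE(d)
    pairs <- MatePairSet(c("F1", "F2", "F3"), c("M1", "M2", "M3"), "g")
    # locus 1: pair genotypes (0,0), (1,2), (1,2) -> scores 2, 1, 1
    o1 <- observedMeanSharing(pairs, ge, 1)
    expect_equal(o1$nPairsUsed, 3L)
    expect_equal(o1$mean, 4 / 3)
    # locus 2: F1 missing -> remaining scores {2-|1-1|, NA male} -> F2xM2
    o2 <- observedMeanSharing(pairs, ge, 2)
    expect_equal(o2$nPairsUsed, 1L)
    expect_equal(o2$mean, 2)
    # locus 3: no informative pair
    o3 <- observedMeanSharing(pairs, ge, 3)
    expect_equal(o3$nPairsUsed, 0L)
    expect_true(is.na(o3$mean))
    expect_error(observedMeanSharing(pairs, ge, "nope"), "not found")
})

test_that("percentile follows the mid-rank convention", {
    expect_equal(percentileOfObserved(0.1, c(0.5, 0.6, 0.7)), 0)
    expect_equal(percentileOfObserved(0.9, c(0.5, 0.6, 0.7)), 1)
    expect_equal(percentileOfObserved(2, rep(2, 100)), 0.5)
    expect_equal(percentileOfObserved(0.6, c(0.5, 0.6, 0.7)), 0.5)
    expect_equal(percentileOfObserved(0.6, c(0.5, 0.55, 0.6, 0.7)),
                 (2 + 0.5) / 4)
    expect_true(is.na(percentileOfObserved(1, rep(NA_real_, 5))))
})

test_that("percentile is monotone in the observed mean", {
    set.seed(42)
    null <- runif(500, 0, 2)
    obs <- sort(runif(50, 0, 2))
    pct <- vapply(obs, percentileOfObserved, numeric(1), null = null)
    expect_true(all(diff(pct) >= 0))
})

test_that("classification uses strict cutoffs", {
    cfg <- AssortConfig()
    expect_equal(classifyLocus(0.01, cfg), "negative")
    expect_equal(classifyLocus(0.98, cfg), "positive")
    expect_equal(classifyLocus(0.025, cfg), "none")
    expect_equal(classifyLocus(0.975, cfg), "none")
    expect_equal(classifyLocus(c(0.5, NA), cfg), c("none", NA))
})

test_that("a monomorphic-genotype locus gives a degenerate null at 2", {
    d <- matrix(1L, nrow = 1, ncol = 6,
                dimnames = list(NULL, c("F1", "F2", "F3",
                                        "M1", "M2", "M3")))
    ge <- toyGE(d)
    pairs <- MatePairSet(c("F1", "F2", "F3"), c("M1", "M2", "M3"), "g")
    null <- permutationNull(pairs, ge, 1, AssortConfig(nPermutations = 200))
    expect_true(all(null == 2))
    expect_equal(percentileOfObserved(2, null), 0.5)
})

test_that("permutation null is reproducible and order-independent", {
    ge <- simulateCohort(SimConfig(nLoci = 10, nFemales = 10, nMales = 10,
                                   nPairs = 10, seed = 2))
    pairs <- simulatePairs(ge, SimConfig(nLoci = 10, nFemales = 10,
                                         nMales = 10, nPairs = 10,
                                         seed = 2))
    cfg <- AssortConfig(nPermutations = 500, seed = 99)
    expect_identical(permutationNull(pairs, ge, 3, cfg),
                     permutationNull(pairs, ge, 3, cfg))
    r1 <- runGroupAssortment(pairs, ge, cfg)
    r2 <- runGroupAssortment(pairs, ge, cfg)
    expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("null mean converges to the 2x2 enumeration oracle", {
    d <- matrix(c(0L, 1L, 2L, 1L), nrow = 1,
                dimnames = list(NULL, c("F1", "F2", "M1", "M2")))
    ge <- toyGE(d)
    pairs <- MatePairSet(c("F1", "F2"), c("M1", "M2"), "g")
    nPerm <- 20000
    null <- permutationNull(pairs, ge, 1,
                            AssortConfig(nPermutations = nPerm, seed = 7,
                                         nullScheme = "resample-males"))
    exact <- exactNullMeans(c(0L, 1L), c(2L, 1L))
    expect_length(exact, 4L)
    se <- sd(exact) / sqrt(nPerm)
    expect_lt(abs(mean(null) - mean(exact)), 3 * se + 1e-12)
    # default scheme against its own oracle: all 2 bijective matchings
    nullP <- permutationNull(pairs, ge, 1,
                             AssortConfig(nPermutations = nPerm, seed = 7))
    exactP <- exactPermNullMeans(c(0L, 1L), c(2L, 1L))
    seP <- sd(exactP) / sqrt(nPerm)
    expect_lt(abs(mean(nullP) - mean(exactP)), 3 * seP + 1e-12)
})

test_that("Monte-Carlo percentile matches 3x3 exhaustive enumeration", {
    fDos <- c(0L, 1L, 2L)
    mDos <- c(1L, 1L, 0L)
    d <- matrix(c(fDos, mDos), nrow = 1,
                dimnames = list(NULL, c("F1", "F2", "F3",
                                        "M1", "M2", "M3")))
    ge <- toyGE(d)
    pairs <- MatePairSet(c("F1", "F2", "F3"), c("M1", "M2", "M3"), "g")
    obs <- observedMeanSharing(pairs, ge, 1)$mean
    exact <- exactNullMeans(fDos, mDos)          # 27 equally likely means
    exactPct <- percentileOfObserved(obs, exact)
    nPerm <- 20000
    null <- permutationNull(pairs, ge, 1,
                            AssortConfig(nPermutations = nPerm, seed = 5,
                                         nullScheme = "resample-males"))
    mcPct <- percentileOfObserved(obs, null)
    se <- sqrt(exactPct * (1 - exactPct) / nPerm)
    expect_lt(abs(mcPct - exactPct), 3 * se + 1e-3)
    # default scheme against the 6-matching enumeration
    exactPctP <- percentileOfObserved(obs, exactPermNullMeans(fDos, mDos))
    nullP <- permutationNull(pairs, ge, 1,
                             AssortConfig(nPermutations = nPerm, seed = 5))
    mcPctP <- percentileOfObserved(obs, nullP)
    seP <- sqrt(max(exactPctP * (1 - exactPctP), 0.25 / 27) / nPerm)
    expect_lt(abs(mcPctP - exactPctP), 3 * seP + 1e-3)
})

test_that("replicate means respect the both-genotyped rule", {
    # one female missing, one male missing: informative assignments only
    d <- matrix(c(0L, NA, 2L, NA), nrow = 1,
                dimnames = list(NULL, c("F1", "F2", "M1", "M2")))
    ge <- toyGE(d)
    pairs <- MatePairSet(c("F1", "F2"), c("M1", "M2"), "g")
    null <- permutationNull(pairs, ge, 1,
                            AssortConfig(nPermutations = 300, seed = 1,
                                         minPairsPerLocus = 1L))
    # only informative assignment is F1 x M1 with score 0
    expect_true(all(null[!is.na(null)] == 0))
})

test_that("group scan flags injected loci and handles low-n loci", {
    cfg <- SimConfig(nLoci = 60, nFemales = 40, nMales = 40, nPairs = 60,
                     seed = 31,
                     assortLoci = data.frame(
                         locus = c(1L, 2L),
                         direction = c("negative", "positive"),
                         beta = c(2, 2)))
    sim <- simulateStudy(cfg)
    ge <- sim$ge
    # blank out one locus entirely to exercise the low-n path
    d <- dosage(ge)
    d[5, ] <- NA_integer_
    assays(ge)$dosage <- d
    res <- runGroupAssortment(sim$pairs, ge,
                              AssortConfig(nPermutations = 3000,
                                           seed = 13))
    expect_equal(nrow(res), 60L)
    expect_equal(res$classification[1], "negative")
    expect_equal(res$classification[2], "positive")
    expect_true(res$low_n[5])
    expect_equal(res$classification[5], "none")
    expect_equal(res$n_pairs_used[5], 0L)
    expect_true(all(res$n_pairs_used <= 60L))
    expect_true(all(res$observed_mean >= 0 & res$observed_mean <= 2,
                    na.rm = TRUE))
    expect_equal(metadata(res)$group, "wild")
})

test_that("empty and degenerate pair sets are rejected", {
    ge <- toyGE(matrix(c(0L, 1L), 1,
                       dimnames = list(NULL, c("F1", "M1"))))
    expect_error(runGroupAssortment(MatePairSet(character(), character(),
                                                "g"), ge),
                 "empty")
    expect_error(permutationNull(MatePairSet("F1", "M1", "g"), ge, 1),
                 "2 distinct males")
})
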