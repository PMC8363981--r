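test_that("individual missingness uses strict 'more than' semantics", {
    d <- matrix(1L, nrow = 10, ncol = 3,
                dimnames = list(NULL, c("A", "B", "C")))
    d[1:3, 1] <- NA   # 0.3 > 0.2 -> removed
    d[1:2, 2] <- NA   # exactly 0.2 -> retained
    ge <- toyGE(d)
    out <- filterIndividuals(ge, 0.20)
    expect_equal(out$removed, "A")
    expect_equal(colnames(out$ge), c("B", "C"))

    clean <- filterIndividuals(toyGE(matrix(1L, 5, 2)), 0.20)
    expect_length(clean$removed, 0L)
    expect_equal(ncol(clean$ge), 2L)
    expect_error(filterIndividuals(toyGE(matrix(NA_integer_, 5, 2)), 0.2),
                 "all individuals")
})

test_that("depth filter bounds are strict and need depths", {
    d <- matrix(1L, nrow = 3, ncol = 3)
    dep <- matrix(c(4L, 4L, 4L,    # mean 4  -> removed (< 5)
                    5L, 5L, 5L,    # mean 5  -> retained (not < 5)
                    40L, 40L, 40L),# mean 40 -> removed (> 30)
                  nrow = 3, byrow = TRUE)
    ge <- toyGE(d, refDepth = dep, altDepth = matrix(0L, 3, 3))
    out <- filterSitesByDepth(ge, 5, 30)
    expect_equal(nrow(out$ge), 1L)
    expect_equal(BiocGenerics::start(rowRanges(out$ge)), 200L)

    expect_error(filterSitesByDepth(toyGE(d), 5, 30), "depths are absent")
})

test_that("missing-genotype individuals can be excluded from mean depth", {
    d <- matrix(c(1L, NA, NA, NA), nrow = 1)
    dep <- matrix(c(20L, 0L, 0L, 0L), nrow = 1)
    ge <- toyGE(d, refDepth = dep, altDepth = matrix(0L, 1, 4))
    # excluding missing individuals: mean 20, retained
    expect_equal(nrow(filterSitesByDepth(ge, 5, 30)$ge), 1L)
    # counting them as zero depth: mean 5, still retained; bound strict
    expect_equal(nrow(filterSitesByDepth(ge, 5, 30,
                                         depthMissing = "zero")$ge), 1L)
    expect_equal(nrow(filterSitesByDepth(ge, 6, 30,
                                         depthMissing = "zero")$ge), 0L)
})

test_that("site missingness uses strict 'greater than' semantics", {
    d <- matrix(1L, nrow = 3, ncol = 10)
    d[1, 1:9] <- NA  # 0.9 > 0.8 -> removed
    d[2, 1:8] <- NA  # exactly 0.8 -> retained
    ge <- toyGE(d)
    out <- filterSitesByMissingness(ge, 0.80)
    expect_equal(nrow(out$ge), 2L)
    expect_length(out$removed, 1L)

    id <- filterSitesByMissingness(toyGE(matrix(0:1, 4, 6)), 0.8)
    expect_equal(nrow(id$ge), 4L)
})

test_that("HDplot flags excess heterozygosity and skewed read ratios", {
    # 10 individuals; rows: H=0.7; symmetric reads; a=90 b=10
    d <- rbind(c(rep(1L, 7), rep(0L, 3)),
               c(rep(1L, 5), rep(0L, 5)),
               c(rep(1L, 5), rep(0L, 5)))
    ref <- rbind(rep(5L, 10), rep(10L, 10), rep(18L, 10))
    alt <- rbind(rep(5L, 10), rep(10L, 10), rep(2L, 10))
    ge <- toyGE(d, refDepth = ref, altDepth = alt)
    st <- hdplotStats(ge)
    expect_equal(st$H, c(0.7, 0.5, 0.5))
    # row 2: a = b = 50 -> D = 0; row 3: a = 90, b = 10 -> D = 80/10 = 8
    expect_equal(st$D[2], 0)
    expect_equal(st$D[3], (90 - 10) / sqrt(100))
    bl <- hdplotParalogs(ge)
    expect_setequal(bl$locus_id, rownames(ge)[c(1, 3)])
    # zero heterozygotes: D = 0, judged on H alone
    hom <- toyGE(matrix(c(0L, 0L, 2L, 2L), 1),
                 refDepth = matrix(10L, 1, 4),
                 altDepth = matrix(10L, 1, 4))
    expect_equal(hdplotStats(hom)$D, 0)
    expect_equal(nrow(hdplotParalogs(hom)), 0L)
})

test_that("filter chain report is consistent and chain is idempotent", {
    ge <- simulateCohort(SimConfig(nLoci = 120, nFemales = 15,
                                   nMales = 15, nPairs = 15,
                                   missingRate = 0.05,
                                   paralogFraction = 0.05,
                                   depthMean = 8, seed = 21))
    cfg <- FilterConfig(minMeanDepth = 6, maxMeanDepth = 12)
    out <- runFilterChain(ge, cfg)
    rep1 <- out$report
    expect_equal(nSitesOut(rep1),
                 rep1@nSitesIn - rep1@nSitesRemovedParalog -
                 rep1@nSitesRemovedDepth - rep1@nSitesRemovedMissing)
    expect_equal(nrow(out$ge), nSitesOut(rep1))
    # idempotence: re-running on the output removes nothing
    out2 <- runFilterChain(out$ge, cfg)
    expect_equal(nSitesOut(out2$report), nrow(out$ge))
    expect_equal(out2$report@nIndividualsRemoved, 0L)
})

test_that("disabled thresholds pass everything through", {
    ge <- simulateCohort(SimConfig(nLoci = 30, nFemales = 6, nMales = 6,
                                   nPairs = 6, missingRate = 0.1,
                                   seed = 5))
    cfg <- FilterConfig(maxIndividualMissing = NA, minMeanDepth = NA,
                        maxMeanDepth = NA, maxSiteMissing = NA,
                        hdMaxHeterozygosity = NA)
    out <- runFilterChain(ge, cfg)
    expect_equal(nrow(out$ge), 30L)
    expect_equal(nSitesOut(out$report), 30L)
    expect_equal(out$report@nSitesRemovedParalog +
                 out$report@nSitesRemovedDepth +
                 out$report@nSitesRemovedMissing, 0L)
})

test_that("a chain where every site fails depth warns and empties", {
    d <- matrix(rep(c(0L, 0L, 1L, 1L), each = 4), 4, 4)  # H = 0.5
    ge <- toyGE(d, refDepth = matrix(1L, 4, 4),
                altDepth = matrix(0L, 4, 4))
    expect_warning(out <- runFilterChain(ge, FilterConfig()),
                   "no sites survive")
    expect_equal(nSitesOut(out$report), 0L)
})

test_that("tightening any threshold never increases surviving sites", {
    ge <- simulateCohort(SimConfig(nLoci = 150, nFemales = 12,
                                   nMales = 12, nPairs = 12,
                                   missingRate = 0.15, depthMean = 7,
                                   paralogFraction = 0.1, seed = 9))
    base <- FilterConfig(minMeanDepth = 5, maxMeanDepth = 12,
                         maxSiteMissing = 0.3,
                         hdMaxHeterozygosity = 0.6)
    nBase <- nSitesOut(runFilterChain(ge, base)$report)
    tighter <- list(
        FilterConfig(minMeanDepth = 6, maxMeanDepth = 12,
                     maxSiteMissing = 0.3, hdMaxHeterozygosity = 0.6),
        FilterConfig(minMeanDepth = 5, maxMeanDepth = 10,
                     maxSiteMissing = 0.3, hdMaxHeterozygosity = 0.6),
        FilterConfig(minMeanDepth = 5, maxMeanDepth = 12,
                     maxSiteMissing = 0.2, hdMaxHeterozygosity = 0.6),
        FilterConfig(minMeanDepth = 5, maxMeanDepth = 12,
                     maxSiteMissing = 0.3, hdMaxHeterozygosity = 0.5))
    for (cfg in tighter)
        expect_lte(nSitesOut(runFilterChain(ge, cfg)$report), nBase)
})

test_that("report arithmetic identity holds on random matrices", {
    for (seed in 1:5) {
        ge <- simulateCohort(SimConfig(nLoci = 80, nFemales = 10,
                                       nMales = 10, nPairs = 10,
                                       missingRate = runif(1, 0, 0.3),
                                       depthMean = runif(1, 4, 20),
                                       paralogFraction = 0.05,
                                       seed = seed))
        r <- suppressWarnings(runFilterChain(ge, FilterConfig())$report)
        expect_equal(r@nSitesIn - r@nSitesRemovedParalog -
                     r@nSitesRemovedDepth - r@nSitesRemovedMissing,
                     nSitesOut(r))
    }
})
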