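Package: MateAssort
Title: Locus-Wise Tests of Non-Random Mate Pairing from Offspring-Derived
    Genotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers positive and negative assortative mating at individual
    SNPs from observed mate pairs and multi-sample genotype data. Genotypes
    are encoded as minor-allele dosage, each mate pair is scored by the
    number of shared allele classes (0, 1 or 2), and the per-locus mean
    score over pairs is compared with a permutation null built by randomly
    re-assigning males to females. Loci in the extreme tails of the null
    are classified as negatively or positively assorting, and the flagged
    SNP sets of two mating groups (for example hatchery- versus
    natural-origin fish) can be compared and annotated against gene models.
    Includes the standard post-calling filter chain for reduced
    representation sequencing data (individual and site missingness, mean
    site depth, HDplot-style paralog detection from heterozygote read
    ratios) and a synthetic-data generator with controllable per-locus
    assortment so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Genetics, SNP, StatisticalMethod, Sequencing
RoxygenNote: 7.3.3
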