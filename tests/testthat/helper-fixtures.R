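# In-code fixture builders shared across test files.

# Tiny GenotypeExperiment from a dosage matrix; one locus per row, loci on
# chr1 at 100, 200, ... unless chrom/pos given. sex defaults to females
# "F*" / males "M*" by column name prefix.
toyGE <- function(d, chrom = NULL, pos = NULL, refDepth = NULL,
                  altDepth = NULL, sex = NULL, encode = FALSE) {
    d <- as.matrix(d)
    if (is.null(colnames(d)))
        colnames(d) <- paste0("I", seq_len(ncol(d)))
    if (is.null(chrom)) chrom <- rep("chr1", nrow(d))
    if (is.null(pos)) pos <- 100L * seq_len(nrow(d))
    if (is.null(sex))
        sex <- ifelse(startsWith(colnames(d), "F"), "female",
               ifelse(startsWith(colnames(d), "M"), "male", NA))
    GenotypeExperiment(d, chrom = chrom, pos = pos,
                       ref = rep("A", nrow(d)), alt = rep("C", nrow(d)),
                       sex = sex, refDepth = refDepth,
                       altDepth = altDepth, encode = encode)
}

# Minimal per-locus classification table for compareGroups tests.
clsTable <- function(ids, classification, chrom = NULL) {
    data.frame(locus_id = ids,
               chrom = if (is.null(chrom)) rep("chr1", length(ids))
                       else chrom,
               pos = seq_along(ids),
               classification = classification,
               stringsAsFactors = FALSE)
}

# Write a small VCF with given genotype strings (loci x samples matrix of
# "0/0" etc.), optional AD strings appended per cell.
writeToyVcf <- function(path, gt, chrom, pos, ref, alt, ad = NULL) {
    fmt <- if (is.null(ad)) "GT" else "GT:AD"
    cells <- if (is.null(ad)) gt else matrix(paste0(gt, ":", ad),
                                             nrow(gt), ncol(gt))
    header <- c("##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        if (!is.null(ad))
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
    body <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", fmt,
                  apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, body), path)
    path
}

# Independent oracle for the pair sharing score: genotypes as allele
# multisets, score = size of the multiset intersection.
sharingOracle <- function(d1, d2) {
    geno <- function(d) c(rep("a", d), rep("A", 2 - d))
    g1 <- geno(d1); g2 <- geno(d2)
    sum(vapply(c("a", "A"), function(al)
        min(sum(g1 == al), sum(g2 == al)), numeric(1)))
}

# Exact null distribution of replicate mean sharing for small pair sets
# under the resample-males scheme: every assignment of one male (with
# replacement) to each female, enumerated exhaustively. Returns the means
# over all length(males)^length(females) equally likely assignments.
exactNullMeans <- function(fDos, mDos) {
    nF <- length(fDos); nM <- length(mDos)
    grid <- as.matrix(expand.grid(rep(list(seq_len(nM)), nF)))
    apply(grid, 1L, function(assign) {
        s <- 2 - abs(fDos - mDos[assign])
        if (all(is.na(s))) NA_real_ else mean(s, na.rm = TRUE)
    })
}

# All permutations of seq_len(n), one per row (n small).
allPerms <- function(n) {
    if (n == 1L) return(matrix(1L, 1, 1))
    sub <- allPerms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
        rest <- seq_len(n)[-i]
        cbind(i, matrix(rest[sub], nrow(sub)))
    }))
}

# Exact null under the default permute-males scheme: every bijective
# matching of the male multiset to the females, enumerated exhaustively.
exactPermNullMeans <- function(fDos, mDos) {
    stopifnot(length(fDos) == length(mDos))
    apply(allPerms(length(mDos)), 1L, function(assign) {
        s <- 2 - abs(fDos - mDos[assign])
        if (all(is.na(s))) NA_real_ else mean(s, na.rm = TRUE)
    })
}
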