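#' Read a multi-sample VCF into a GenotypeExperiment
#'
#' Parses a VCF (via \pkg{VariantAnnotation}), keeps biallelic SNP records
#' only (multiallelic records and indels are skipped, with a message giving
#' the count), and encodes genotypes as minor-allele dosage with the minor
#' allele determined per locus from allele frequencies over all genotyped
#' individuals. Missing genotypes (\code{./.}) become \code{NA}. When the
#' VCF carries an \code{AD} FORMAT field, per-genotype (ref, alt) read
#' depths are attached; these power the depth and paralog filters.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param metadata a data.frame (or path to a TSV/CSV) with columns
#'   \code{id}, \code{sex} (\code{"female"}/\code{"male"}) and optionally
#'   \code{origin}. Samples present in the VCF but absent from the metadata
#'   are kept with a warning and \code{origin = "unknown"}.
#' @return a \linkS4class{GenotypeExperiment}.
#' @export
readGenotypeVcf <- function(path, metadata = NULL) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    refA <- as.character(rr$REF)
    altL <- rr$ALT
    nAlt <- S4Vectors::elementNROWS(altL)
    altA <- rep(NA_character_, length(rr))
    altA[nAlt == 1L] <- as.character(unlist(altL[nAlt == 1L]))
    keep <- nAlt == 1L & nchar(refA) == 1L & !is.na(altA) &
        nchar(altA) == 1L & altA %in% c("A", "C", "G", "T") &
        refA %in% c("A", "C", "G", "T")
    nSkipped <- sum(!keep)
    if (nSkipped > 0)
        message(nSkipped, " multiallelic/indel record(s) skipped")
    if (!any(keep))
        stop("no biallelic SNP records in ", path)
    gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
    d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    d[gt %in% c("0/0", "0|0")] <- 0L
    d[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    d[gt %in% c("1/1", "1|1")] <- 2L
    refDepth <- altDepth <- NULL
    ad <- VariantAnnotation::geno(vcf)$AD
    if (!is.null(ad)) {
        ad <- ad[keep, , drop = FALSE]
        refDepth <- apply(ad, c(1, 2), function(x) {
            x <- x[[1]]; if (length(x) < 1 || is.na(x[1])) NA_integer_
            else as.integer(x[1]) })
        altDepth <- apply(ad, c(1, 2), function(x) {
            x <- x[[1]]; if (length(x) < 2 || is.na(x[2])) NA_integer_
            else as.integer(x[2]) })
    }
    samp <- colnames(gt)
    sex <- rep(NA_character_, length(samp))
    origin <- rep("unknown", length(samp))
    if (!is.null(metadata)) {
        md <- readCohortMetadata(metadata)
        hit <- match(samp, md$id)
        unknown <- samp[is.na(hit)]
        if (length(unknown))
            warning("sample(s) absent from metadata, origin set to ",
                    "'unknown': ", paste(unknown, collapse = ", "))
        sex[!is.na(hit)] <- md$sex[hit[!is.na(hit)]]
        if (!is.null(md$origin))
            origin[!is.na(hit)] <- md$origin[hit[!is.na(hit)]]
    }
    rrk <- rr[keep]
    GenotypeExperiment(d,
        chrom = as.character(GenomeInfoDb::seqnames(rrk)),
        pos = BiocGenerics::start(rrk),
        ref = refA[keep], alt = altA[keep],
        sex = sex, origin = origin,
        refDepth = refDepth, altDepth = altDepth)
}

# Accept a data.frame or a delimited file with columns id/sex[/origin].
readCohortMetadata <- function(metadata) {
    if (is.character(metadata) && length(metadata) == 1L)
        metadata <- readDelimited(metadata)
    metadata <- as.data.frame(metadata)
    stopifnot(all(c("id", "sex") %in% colnames(metadata)))
    metadata$id <- as.character(metadata$id)
    metadata
}

# Delimiter sniffing: tab if the header contains one, else comma.
readDelimited <- function(path) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
               na.strings = c("NA", ""))
}

#' Write a GenotypeExperiment as VCF
#'
#' Emits a minimal VCF 4.2 with GT (and AD when depths are present) FORMAT
#' fields. Genotypes are written against the recorded ref/alt alleles, i.e.
#' minor-allele dosage is converted back to alt-allele counts, so a
#' write/read round trip preserves dosage, missingness and locus keys
#' exactly.
#'
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypeVcf <- function(ge, path) {
    d <- dosage(ge)
    minorIsAlt <- rowData(ge)$minorIsAlt
    flip <- which(!is.na(minorIsAlt) & !minorIsAlt)
    if (length(flip)) d[flip, ] <- 2L - d[flip, , drop = FALSE]
    gtStr <- matrix("./.", nrow(d), ncol(d))
    gtStr[!is.na(d) & d == 0L] <- "0/0"
    gtStr[!is.na(d) & d == 1L] <- "0/1"
    gtStr[!is.na(d) & d == 2L] <- "1/1"
    fmt <- "GT"
    if (hasDepths(ge)) {
        ad <- alleleDepths(ge)
        adStr <- matrix(paste0(ifelse(is.na(ad$ref), ".", ad$ref), ",",
                               ifelse(is.na(ad$alt), ".", ad$alt)),
                        nrow(d), ncol(d))
        gtStr <- matrix(paste0(gtStr, ":", adStr), nrow(d), ncol(d))
        fmt <- "GT:AD"
    }
    rr <- rowRanges(ge)
    header <- c("##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        if (hasDepths(ge))
            paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
                   "\"Allelic depths (ref,alt)\">"),
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(ge)), collapse = "\t"))
    body <- paste(as.character(GenomeInfoDb::seqnames(rr)),
                  BiocGenerics::start(rr), rownames(ge),
                  rowData(ge)$ref, rowData(ge)$alt, ".", "PASS", ".", fmt,
                  apply(gtStr, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read a mate-pair table
#'
#' Reads a tab- or comma-delimited table with columns \code{female_id},
#' \code{male_id} and optionally \code{group}, validates each pair against
#' the cohort (ids must exist with the expected sex), and drops duplicate
#' rows within a group with a warning.
#'
#' @param path path to the pair table.
#' @param cohort optional \linkS4class{GenotypeExperiment} used for
#'   validation; strongly recommended.
#' @param defaultGroup group label used when the table has no \code{group}
#'   column.
#' @return a named list of \linkS4class{MatePairSet}, one element per group
#'   label in the table.
#' @export
readMatePairs <- function(path, cohort = NULL, defaultGroup = "all") {
    tab <- readDelimited(path)
    if (!all(c("female_id", "male_id") %in% colnames(tab)))
        stop("pair table must have columns female_id and male_id")
    tab$female_id <- as.character(tab$female_id)
    tab$male_id <- as.character(tab$male_id)
    if (is.null(tab$group)) tab$group <- defaultGroup
    if (!is.null(cohort)) {
        ids <- colnames(cohort)
        sex <- setNames(as.character(colData(cohort)$sex), ids)
        for (i in seq_len(nrow(tab))) {
            f <- tab$female_id[i]; m <- tab$male_id[i]
            if (!(f %in% ids) || !(m %in% ids))
                stop("row ", i, ": unknown individual '",
                     if (f %in% ids) m else f, "'")
            if (!identical(sex[[f]], "female") ||
                !identical(sex[[m]], "male"))
                stop("row ", i, ": sex mismatch for pair (", f, ", ", m,
                     "); expected female_id then male_id")
        }
    }
    out <- lapply(split(tab, tab$group), function(g) {
        key <- paste(g$female_id, g$male_id, sep = "\r")
        if (anyDuplicated(key)) {
            warning(sum(duplicated(key)), " duplicate pair(s) dropped in ",
                    "group '", g$group[1], "'")
            g <- g[!duplicated(key), , drop = FALSE]
        }
        MatePairSet(g$female_id, g$male_id, groupLabel = g$group[1])
    })
    out[order(names(out))]
}

#' Write a mate-pair table
#'
#' @param pairs a \linkS4class{MatePairSet} or a list of them.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeMatePairs <- function(pairs, path) {
    if (is(pairs, "MatePairSet")) pairs <- list(pairs)
    tab <- do.call(rbind, lapply(pairs, as.data.frame))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.RESULT_COLS <- c("chrom", "pos", "ref", "alt", "locus_id", "n_pairs_used",
                  "observed_mean", "null_mean", "null_sd", "percentile",
                  "classification")

#' Write per-locus assortment results
#'
#' Serialises the table returned by [runGroupAssortment()] as UTF-8 TSV
#' with a fixed column order (locus fields, \code{n_pairs_used},
#' \code{observed_mean}, \code{null_mean}, \code{null_sd},
#' \code{percentile}, \code{classification}), rows ordered by
#' (chromosome, position), and \code{NA} for missing values.
#'
#' @param results a data.frame/DataFrame of per-locus results.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeAssortResults <- function(results, path) {
    results <- as.data.frame(results)
    stopifnot(all(.RESULT_COLS %in% colnames(results)))
    results <- results[order(results$chrom, results$pos), .RESULT_COLS,
                       drop = FALSE]
    write.table(results, path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
    invisible(path)
}

#' Read back a per-locus assortment results table
#'
#' @param path a TSV written by [writeAssortResults()].
#' @return a data.frame.
#' @export
readAssortResults <- function(path) {
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               na.strings = "NA", colClasses = c(chrom = "character"))
}

#' Read gene features from GFF3
#'
#' Imports a GFF3 via \pkg{rtracklayer} and keeps records of type
#' \code{"gene"} only — annotation is against the gene body itself, not
#' transcripts, exons, or any upstream/downstream window.
#'
#' @param path path to a GFF3 file.
#' @return a \code{GRanges} with metadata columns \code{gene_id} and
#'   \code{gene_name} (1-based inclusive coordinates, GFF3 native).
#' @export
readGeneFeatures <- function(path) {
    gff <- rtracklayer::import(path, format = "gff3")
    genes <- gff[!is.na(gff$type) & as.character(gff$type) == "gene"]
    geneId <- if (!is.null(genes$ID)) as.character(genes$ID)
              else rep(NA_character_, length(genes))
    geneName <- if (!is.null(genes$Name)) as.character(genes$Name)
                else rep(NA_character_, length(genes))
    out <- GRanges(GenomeInfoDb::seqnames(genes), IRanges::ranges(genes),
                   strand = BiocGenerics::strand(genes))
    mcols(out)$gene_id <- geneId
    mcols(out)$gene_name <- geneName
    out
}
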