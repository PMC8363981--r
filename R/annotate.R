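#' Annotate SNPs with containing genes
#'
#' A SNP is annotated with a gene iff its position lies within the gene
#' body: \code{gene.start <= pos <= gene.end} on the same sequence,
#' 1-based inclusive on both ends (GFF3 native coordinates). No upstream
#' or downstream window is applied, and strand never affects containment.
#' SNPs inside no gene are kept with \code{NA} gene fields; a SNP inside
#' several overlapping genes yields one row per gene.
#'
#' @param loci a \code{GRanges} of SNP positions, or a per-locus result
#'   table with \code{chrom} and \code{pos} columns (classification
#'   columns, when present, are carried through to the output).
#' @param geneFeatures a \code{GRanges} of gene features with
#'   \code{gene_id} and \code{gene_name} metadata columns, e.g. from
#'   [readGeneFeatures()].
#' @return a data.frame with one row per (SNP, containing gene) — or per
#'   SNP with NA gene fields when it hits no gene.
#' @export
annotateSnps <- function(loci, geneFeatures) {
    if (is(loci, "GRanges")) {
        gr <- loci
        extra <- as.data.frame(mcols(gr))
        ids <- if (!is.null(names(gr))) names(gr)
               else makeLocusIds(as.character(GenomeInfoDb::seqnames(gr)),
                                 BiocGenerics::start(gr), ".", ".")
    } else {
        tab <- as.data.frame(loci)
        stopifnot(all(c("chrom", "pos") %in% colnames(tab)))
        gr <- GRanges(tab$chrom, IRanges(tab$pos, width = 1L))
        keep <- intersect(c("classification", "percentile",
                            "observed_mean"), colnames(tab))
        extra <- tab[, keep, drop = FALSE]
        ids <- if ("locus_id" %in% colnames(tab)) tab$locus_id
               else makeLocusIds(tab$chrom, tab$pos, ".", ".")
    }
    lev <- union(GenomeInfoDb::seqlevels(gr),
                 GenomeInfoDb::seqlevels(geneFeatures))
    GenomeInfoDb::seqlevels(gr) <- lev
    GenomeInfoDb::seqlevels(geneFeatures) <- lev
    hits <- findOverlaps(gr, geneFeatures, type = "within",
                         ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    nohit <- setdiff(seq_along(gr), qi)
    rowIdx <- c(qi, nohit)
    out <- data.frame(
        locus_id = ids[rowIdx],
        chrom = as.character(GenomeInfoDb::seqnames(gr))[rowIdx],
        pos = BiocGenerics::start(gr)[rowIdx],
        gene_id = c(geneFeatures$gene_id[si],
                    rep(NA_character_, length(nohit))),
        gene_name = c(geneFeatures$gene_name[si],
                      rep(NA_character_, length(nohit))),
        stringsAsFactors = FALSE)
    if (ncol(extra))
        out <- cbind(out, extra[rowIdx, , drop = FALSE])
    out <- out[order(out$chrom, out$pos, out$gene_id,
                     na.last = TRUE), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write a SNP-in-gene annotation table
#'
#' @param annotation data.frame from [annotateSnps()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotation <- function(annotation, path) {
    write.table(annotation, path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
    invisible(path)
}
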