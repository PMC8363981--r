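#' Construct a GenotypeExperiment
#'
#' Builds the package's central container from a dosage matrix and locus /
#' individual metadata. Dosage is re-encoded against the per-locus minor
#' allele unless \code{encode = FALSE} (see [encodeMinorAllele()]).
#'
#' @param dosage integer matrix, loci in rows, individuals in columns;
#'   values 0/1/2 count copies of the alternate allele on input (they count
#'   the minor allele after encoding), \code{NA} marks a missing genotype.
#' @param chrom,pos,ref,alt per-locus vectors: chromosome, 1-based position,
#'   reference and alternate allele.
#' @param sex,origin per-individual vectors; \code{sex} must be
#'   \code{"female"}/\code{"male"} for any individual later referenced by a
#'   \linkS4class{MatePairSet}.
#' @param refDepth,altDepth optional matrices of per-genotype read counts,
#'   same shape as \code{dosage}.
#' @param encode logical; re-encode dosage to minor-allele dosage (default
#'   \code{TRUE}).
#' @return a \linkS4class{GenotypeExperiment}.
#' @export
#' @examples
#' d <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 2,
#'             dimnames = list(NULL, c("F1", "M1", "M2")))
#' ge <- GenotypeExperiment(d, chrom = c("chr1", "chr1"), pos = c(100L, 200L),
#'                          ref = c("A", "G"), alt = c("C", "T"),
#'                          sex = c("female", "male", "male"))
#' dosage(ge)
GenotypeExperiment <- function(dosage, chrom, pos, ref, alt,
                               sex = NULL, origin = NULL,
                               refDepth = NULL, altDepth = NULL,
                               encode = TRUE) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    nLoci <- nrow(dosage)
    stopifnot(length(chrom) == nLoci, length(pos) == nLoci,
              length(ref) == nLoci, length(alt) == nLoci)
    if (is.null(colnames(dosage)))
        colnames(dosage) <- paste0("ind", seq_len(ncol(dosage)))
    rr <- GRanges(seqnames = as.character(chrom),
                  ranges = IRanges(start = as.integer(pos), width = 1L))
    mcols(rr)$ref <- as.character(ref)
    mcols(rr)$alt <- as.character(alt)
    names(rr) <- makeLocusIds(chrom, pos, ref, alt)
    rownames(dosage) <- names(rr)
    cd <- DataFrame(row.names = colnames(dosage))
    cd$sex <- if (is.null(sex)) rep(NA_character_, ncol(dosage))
              else as.character(sex)
    cd$origin <- if (is.null(origin)) rep("unknown", ncol(dosage))
                 else as.character(origin)
    assayList <- list(dosage = dosage)
    if (!is.null(refDepth) || !is.null(altDepth)) {
        stopifnot(!is.null(refDepth), !is.null(altDepth))
        refDepth <- as.matrix(refDepth); altDepth <- as.matrix(altDepth)
        storage.mode(refDepth) <- "integer"
        storage.mode(altDepth) <- "integer"
        stopifnot(identical(dim(refDepth), dim(dosage)),
                  identical(dim(altDepth), dim(dosage)))
        dimnames(refDepth) <- dimnames(altDepth) <- dimnames(dosage)
        assayList$refDepth <- refDepth
        assayList$altDepth <- altDepth
    }
    se <- SummarizedExperiment(assays = assayList, rowRanges = rr,
                               colData = cd)
    ge <- new("GenotypeExperiment", se)
    if (encode) ge <- encodeMinorAllele(ge) else {
        rowData(ge)$minorIsAlt <- rep(NA, nLoci)
        rowData(ge)$maf <- rep(NA_real_, nLoci)
    }
    ge
}

#' Re-encode dosage against the per-locus minor allele
#'
#' For each locus the allele frequencies are computed over all genotyped
#' individuals in the object. If the allele currently being counted has
#' frequency above 0.5 the dosage is flipped (\code{d -> 2 - d}) so that
#' dosage always counts the minor allele. On an exact 0.5 tie the alternate
#' allele is designated minor, which makes the operation deterministic and
#' idempotent; the pair sharing score is invariant to the choice in any
#' case, since \code{|d1 - d2|} is unchanged by flipping both dosages.
#'
#' Row metadata columns \code{minorIsAlt} and \code{maf} are (re)computed.
#' Allele depths always stay in (ref, alt) orientation.
#'
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @return the re-encoded \linkS4class{GenotypeExperiment}.
#' @export
encodeMinorAllele <- function(ge) {
    d <- assay(ge, "dosage")
    wasAlt <- rowData(ge)$minorIsAlt
    # dosage currently counts alt allele where minorIsAlt is TRUE or unset,
    # and ref where FALSE; normalise to alt-dosage first
    if (!is.null(wasAlt)) {
        flip <- which(!is.na(wasAlt) & !wasAlt)
        if (length(flip)) d[flip, ] <- 2L - d[flip, , drop = FALSE]
    }
    nGeno <- rowSums(!is.na(d))
    altCount <- rowSums(d, na.rm = TRUE)
    altFreq <- ifelse(nGeno > 0, altCount / (2 * nGeno), 0)
    minorIsAlt <- altFreq <= 0.5          # tie: alt designated minor
    flip <- which(!minorIsAlt)
    if (length(flip)) d[flip, ] <- 2L - d[flip, , drop = FALSE]
    assays(ge)$dosage <- d
    rowData(ge)$minorIsAlt <- minorIsAlt
    rowData(ge)$maf <- pmin(altFreq, 1 - altFreq)
    validObject(ge)
    ge
}

#' @describeIn GenotypeExperiment-accessors minor-allele dosage matrix
#'   (loci x individuals).
#' @export
dosage <- function(ge) assay(ge, "dosage")

#' Accessors for GenotypeExperiment
#'
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @name GenotypeExperiment-accessors
#' @return \code{dosage()} the integer dosage matrix; \code{alleleDepths()}
#'   a list with \code{ref} and \code{alt} matrices or \code{NULL};
#'   \code{locusIds()} the locus keys; \code{hasDepths()} a logical.
NULL

#' @describeIn GenotypeExperiment-accessors read-depth matrices, or NULL if
#'   the object carries no depths.
#' @export
alleleDepths <- function(ge) {
    if (!hasDepths(ge)) return(NULL)
    list(ref = assay(ge, "refDepth"), alt = assay(ge, "altDepth"))
}

#' @describeIn GenotypeExperiment-accessors TRUE if allele depths are present.
#' @export
hasDepths <- function(ge) {
    all(c("refDepth", "altDepth") %in% assayNames(ge))
}

#' @describeIn GenotypeExperiment-accessors locus keys
#'   ("chrom:pos_ref/alt").
#' @export
locusIds <- function(ge) rownames(ge)

setMethod("show", "GenotypeExperiment", function(object) {
    cat(sprintf("GenotypeExperiment: %d loci x %d individuals\n",
                nrow(object), ncol(object)))
    sx <- colData(object)$sex
    cat(sprintf("  sex: %d female, %d male, %d unspecified\n",
                sum(sx == "female", na.rm = TRUE),
                sum(sx == "male", na.rm = TRUE), sum(is.na(sx))))
    og <- table(colData(object)$origin)
    cat("  origin:", paste(names(og), og, sep = "=", collapse = ", "), "\n")
    d <- assay(object, "dosage")
    cat(sprintf("  missing genotypes: %.2f%%; allele depths: %s\n",
                100 * mean(is.na(d)),
                if (hasDepths(object)) "present" else "absent"))
})
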