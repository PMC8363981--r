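#' Compare two groups' per-locus classifications
#'
#' Outer-joins the two result tables on \code{locus_id} (a locus absent
#' from one side counts as \code{"none"} there) and tallies: per-group
#' negative/positive counts, loci sharing the same non-\code{"none"}
#' classification (shared negative / shared positive, their sum being the
#' same-direction count), and loci flagged in both groups with opposite
#' signs. Shared percentages are \code{100 * shared / (count_a + count_b)}
#' — the sum of the two groups' flagged counts, not their union (see the
#' vignette for the rationale behind this denominator convention).
#'
#' @param resultsA,resultsB per-locus result tables from
#'   [runGroupAssortment()] (or any table with \code{locus_id} and
#'   \code{classification} columns; \code{chrom} is used for the
#'   per-chromosome breakdown when present).
#' @param labelA,labelB group labels; default to the tables' metadata, or
#'   "A"/"B".
#' @return a \linkS4class{GroupComparison}.
#' @export
compareGroups <- function(resultsA, resultsB, labelA = NULL,
                          labelB = NULL) {
    labelA <- labelA %||% metadataLabel(resultsA, "A")
    labelB <- labelB %||% metadataLabel(resultsB, "B")
    a <- as.data.frame(resultsA)
    b <- as.data.frame(resultsB)
    for (nm in c("a", "b")) {
        x <- get(nm)
        if (anyDuplicated(x$locus_id))
            stop("duplicate locus_id in results ", toupper(nm))
    }
    universe <- union(a$locus_id, b$locus_id)
    clsOf <- function(x) {
        cls <- x$classification[match(universe, x$locus_id)]
        ifelse(is.na(cls), "none", cls)
    }
    ca <- clsOf(a); cb <- clsOf(b)
    chrom <- a$chrom[match(universe, a$locus_id)]
    if ("chrom" %in% colnames(b)) {
        fill <- is.na(chrom)
        chrom[fill] <- b$chrom[match(universe[fill], b$locus_id)]
    }
    chrom[is.na(chrom)] <- "unplaced"

    nNegA <- sum(ca == "negative"); nPosA <- sum(ca == "positive")
    nNegB <- sum(cb == "negative"); nPosB <- sum(cb == "positive")
    sharedNeg <- sum(ca == "negative" & cb == "negative")
    sharedPos <- sum(ca == "positive" & cb == "positive")
    opposite <- sum((ca == "negative" & cb == "positive") |
                    (ca == "positive" & cb == "negative"))
    pctOf <- function(shared, na, nb)
        if (na + nb > 0) 100 * shared / (na + nb) else NA_real_

    perChrom <- do.call(rbind, lapply(sort(unique(chrom)), function(ch) {
        i <- chrom == ch
        data.frame(chrom = ch,
                   neg_a = sum(ca[i] == "negative"),
                   pos_a = sum(ca[i] == "positive"),
                   neg_b = sum(cb[i] == "negative"),
                   pos_b = sum(cb[i] == "positive"),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(perChrom))
        perChrom <- data.frame(chrom = character(), neg_a = integer(),
                               pos_a = integer(), neg_b = integer(),
                               pos_b = integer())

    new("GroupComparison", groupALabel = labelA, groupBLabel = labelB,
        nNegativeA = nNegA, nNegativeB = nNegB,
        nPositiveA = nPosA, nPositiveB = nPosB,
        sharedNegative = sharedNeg, sharedPositive = sharedPos,
        pctSharedNegative = pctOf(sharedNeg, nNegA, nNegB),
        pctSharedPositive = pctOf(sharedPos, nPosA, nPosB),
        sameDirection = sharedNeg + sharedPos,
        oppositeDirection = opposite,
        perChromosome = perChrom)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

metadataLabel <- function(results, fallback) {
    md <- tryCatch(metadata(results), error = function(e) NULL)
    if (!is.null(md$group)) md$group else fallback
}

#' Per-chromosome counts of flagged loci
#'
#' Partitions a group's negative/positive classifications by chromosome,
#' suitable for a per-chromosome bar summary. Loci without a chromosome
#' fall in an \code{"unplaced"} bucket.
#'
#' @param results a per-locus result table with \code{classification} and
#'   (optionally) \code{chrom} columns.
#' @return data.frame with columns \code{chrom}, \code{n_negative},
#'   \code{n_positive}; zero rows for empty input.
#' @export
summarizeByChromosome <- function(results) {
    x <- as.data.frame(results)
    if (nrow(x) == 0L)
        return(data.frame(chrom = character(), n_negative = integer(),
                          n_positive = integer()))
    chrom <- if ("chrom" %in% colnames(x)) x$chrom
             else rep(NA_character_, nrow(x))
    chrom[is.na(chrom)] <- "unplaced"
    do.call(rbind, lapply(sort(unique(chrom)), function(ch) {
        i <- chrom == ch
        data.frame(chrom = ch,
                   n_negative = sum(x$classification[i] == "negative"),
                   n_positive = sum(x$classification[i] == "positive"),
                   stringsAsFactors = FALSE)
    }))
}

#' Write a group comparison
#'
#' JSON summary of the overlap counts plus a per-chromosome TSV.
#'
#' @param comparison a \linkS4class{GroupComparison}.
#' @param jsonPath,tsvPath output paths (either may be NULL to skip).
#' @return invisibly, the comparison.
#' @export
writeGroupComparison <- function(comparison, jsonPath = NULL,
                                 tsvPath = NULL) {
    if (!is.null(jsonPath))
        jsonlite::write_json(as.list(comparison), jsonPath,
                             auto_unbox = TRUE, digits = NA)
    if (!is.null(tsvPath))
        write.table(comparison@perChromosome, tsvPath, sep = "\t",
                    quote = FALSE, row.names = FALSE)
    invisible(comparison)
}
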