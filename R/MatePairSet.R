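#' Construct a MatePairSet
#'
#' @param female,male character vectors of individual ids, one entry per
#'   observed pair.
#' @param groupLabel single group label, e.g. \code{"wild"}.
#' @param cohort optional \linkS4class{GenotypeExperiment}; when supplied,
#'   every id must exist in the cohort with the matching sex.
#' @return a \linkS4class{MatePairSet}.
#' @export
#' @examples
#' MatePairSet(female = c("F1", "F1"), male = c("M1", "M2"),
#'             groupLabel = "wild")
MatePairSet <- function(female, male, groupLabel = "all", cohort = NULL) {
    mp <- new("MatePairSet", groupLabel = as.character(groupLabel),
              female = as.character(female), male = as.character(male))
    if (!is.null(cohort)) validatePairs(mp, cohort)
    mp
}

# Check a MatePairSet against a cohort: every id present, sexes correct.
validatePairs <- function(pairs, cohort) {
    ids <- colnames(cohort)
    sex <- setNames(as.character(colData(cohort)$sex), ids)
    missing <- setdiff(c(pairs@female, pairs@male), ids)
    if (length(missing))
        stop("pair references unknown individual(s): ",
             paste(unique(missing), collapse = ", "))
    badF <- pairs@female[sex[pairs@female] != "female" |
                         is.na(sex[pairs@female])]
    badM <- pairs@male[sex[pairs@male] != "male" | is.na(sex[pairs@male])]
    if (length(badF) || length(badM))
        stop("sex mismatch in pair table: ",
             paste(unique(c(badF, badM)), collapse = ", "),
             " (females must be column 1, males column 2)")
    invisible(TRUE)
}

#' @describeIn MatePairSet-accessors number of pairs.
#' @export
setMethod("length", "MatePairSet", function(x) length(x@female))

#' Accessors for MatePairSet
#'
#' @param x,pairs a \linkS4class{MatePairSet}.
#' @name MatePairSet-accessors
NULL

#' @describeIn MatePairSet-accessors female ids, one per pair.
#' @export
females <- function(pairs) pairs@female

#' @describeIn MatePairSet-accessors male ids, one per pair.
#' @export
males <- function(pairs) pairs@male

#' @describeIn MatePairSet-accessors the group label.
#' @export
groupLabel <- function(pairs) pairs@groupLabel

setMethod("show", "MatePairSet", function(object) {
    cat(sprintf("MatePairSet '%s': %d pairs (%d females, %d males)\n",
                object@groupLabel, length(object),
                length(unique(object@female)),
                length(unique(object@male))))
})

#' @describeIn MatePairSet-accessors coerce to a data.frame with columns
#'   female_id, male_id, group.
#' @export
setMethod("as.data.frame", "MatePairSet", function(x, ...) {
    data.frame(female_id = x@female, male_id = x@male,
               group = rep(x@groupLabel, length(x)))
})
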