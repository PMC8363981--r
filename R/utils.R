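# Small internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to a fixed number of decimal places with ties going away from zero
#' (half-up for positive values), the convention used when formatting shared
#' percentages in comparison tables. Base \code{round()} rounds half to even,
#' which would not reproduce conventionally formatted percentages.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' roundHalfUp(3.1928, 2) # 3.19
#' roundHalfUp(0.125, 2)  # 0.13 (round() would give 0.12)
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic per-stream seed derivation so per-locus RNG streams do not
# depend on processing order. Kept below 2^31 - 1.
deriveSeed <- function(seed, k) {
    as.integer((as.double(seed) + as.double(k) * 1000003) %% 2147483629)
}

# Counts of dosage values 0, 1, 2 and NA in an integer/numeric vector.
dosageCounts <- function(d) {
    c(`0` = sum(d == 0L, na.rm = TRUE),
      `1` = sum(d == 1L, na.rm = TRUE),
      `2` = sum(d == 2L, na.rm = TRUE),
      `NA` = sum(is.na(d)))
}

# Stable locus key "chrom:pos_ref/alt"
makeLocusIds <- function(chrom, pos, ref, alt) {
    paste0(chrom, ":", pos, "_", ref, "/", alt)
}

.msg <- function(verbose, ...) {
    if (isTRUE(verbose)) message(...)
    invisible(NULL)
}
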