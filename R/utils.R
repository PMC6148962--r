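#' @importFrom methods new validObject is setClass setGeneric setMethod setValidity show
#' @importFrom stats median cor cor.test t.test wilcox.test kruskal.test p.adjust
#'   pchisq rnorm runif rexp rbinom rlnorm setNames complete.cases quantile sd
#' @importFrom utils read.delim write.table head
NULL

# canonical amino-acid alphabet (20 letters)
AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

CHROM_LABELS <- c(as.character(1:22), "X", "Y")

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (the convention
#' used when reporting percentages), unlike base [round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfAway <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count, rounded as printed
#'
#' Computes `100 * count / total` rounded half-away-from-zero to the requested
#' number of decimals, matching how summary percentages are reported.
#'
#' @param count numerator count.
#' @param total denominator count (> 0).
#' @param digits decimals to keep (default 2).
#' @return numeric percentage.
#' @examples
#' percentOf(656, 1386)   # 47.33
#' percentOf(462, 2136, digits = 1)  # 21.6
#' @export
percentOf <- function(count, total, digits = 2) {
  if (any(total <= 0)) stop("total must be positive")
  roundHalfAway(100 * count / total, digits)
}

stopIfMissingCols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")))
  }
}

checkCanonicalAA <- function(seqs, allow_extended = FALSE, what = "sequence") {
  alphabet <- AA_CANONICAL
  if (allow_extended) alphabet <- c(alphabet, "U", "B", "Z", "X")
  bad <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    any(!ch %in% alphabet)
  }, logical(1))
  if (any(bad)) {
    stop(sprintf("non-canonical amino acid letter(s) in %s: %s", what,
                 paste(utils::head(names(seqs)[bad], 5), collapse = ", ")))
  }
  invisible(TRUE)
}

# map I -> L for isobaric folding comparisons
foldIL <- function(x) chartr("I", "L", x)
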