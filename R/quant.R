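#' Reads per kilobase of exon per million mapped reads
#'
#' `RPKM = exon_reads / ((mapped_reads / 1e6) * (exon_length / 1e3))`.
#'
#' @param exon_reads total reads falling in the gene's exons.
#' @param mapped_reads total mapped reads of the sample (> 0).
#' @param exon_length summed exon length in bases (> 0).
#' @return RPKM value(s); vectorized.
#' @examples
#' rpkm(1000, 1e6, 1000)  # 1000
#' @export
rpkm <- function(exon_reads, mapped_reads, exon_length) {
  if (any(mapped_reads <= 0)) stop("mapped_reads must be positive")
  if (any(exon_length <= 0)) stop("exon_length must be positive")
  exon_reads / ((mapped_reads / 1e6) * (exon_length / 1e3))
}

#' Log2 transform and per-sample median centering
#'
#' Label-free normalization: intensities are log2-transformed and each
#' sample (column) is centered by subtracting its median over non-missing
#' entries, so every column median becomes 0. Zero intensities are treated
#' as missing before the log (configurable), matching label-free practice.
#' Requires a matrix tagged `raw`; the result is tagged `log2`.
#'
#' @param se `SummarizedExperiment` from [readQuantMatrix()] with
#'   `metadata()$scale == "raw"`.
#' @param zero_as_missing convert zeros to missing before log2 (default
#'   TRUE); with FALSE a zero is an error.
#' @return normalized `SummarizedExperiment` (scale `"log2"`); the column
#'   medians that were subtracted are stored in `metadata()$centering`.
#' @export
log2MedianNormalize <- function(se, zero_as_missing = TRUE) {
  sc <- S4Vectors::metadata(se)$scale
  if (!identical(sc, "raw")) {
    stop("matrix is tagged '", sc, "'; log2 transform is applied to raw ",
         "intensities exactly once")
  }
  m <- SummarizedExperiment::assay(se, "abundance")
  if (any(m == 0, na.rm = TRUE)) {
    if (zero_as_missing) m[m == 0] <- NA else stop("zero intensity with zero_as_missing = FALSE")
  }
  m <- log2(m)
  med <- apply(m, 2, median, na.rm = TRUE)
  if (any(is.na(med))) {
    stop("column(s) fully missing: ",
         paste(colnames(m)[is.na(med)], collapse = ", "))
  }
  m <- sweep(m, 2, med)
  out <- se
  SummarizedExperiment::assay(out, "abundance") <- m
  S4Vectors::metadata(out)$scale <- "log2"
  S4Vectors::metadata(out)$centering <- med
  out
}

#' Re-center a log2 matrix at zero column medians
#'
#' Median-centering only; idempotent (applying it to its own output changes
#' nothing).
#'
#' @param se `SummarizedExperiment` tagged `log2`.
#' @return centered `SummarizedExperiment`.
#' @export
medianCenter <- function(se) {
  if (!identical(S4Vectors::metadata(se)$scale, "log2")) {
    stop("medianCenter expects a log2-scale matrix")
  }
  m <- SummarizedExperiment::assay(se, "abundance")
  med <- apply(m, 2, median, na.rm = TRUE)
  SummarizedExperiment::assay(se, "abundance") <- sweep(m, 2, med)
  se
}

#' Keep features quantified in every sample
#'
#' Complete-case filter: retains the features with no missing value across
#' all samples.
#'
#' @param se `SummarizedExperiment`.
#' @return filtered `SummarizedExperiment`.
#' @export
completeCaseFilter <- function(se) {
  m <- SummarizedExperiment::assay(se, "abundance")
  se[rowSums(is.na(m)) == 0, ]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH q-values: sort p ascending, take the running minimum of
#' `p * m / rank` from the largest rank down, clip at 1, return in input
#' order. Delegates to [stats::p.adjust()] after validating the inputs.
#'
#' @param p vector of p-values in [0, 1].
#' @return q-values in input order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Two-sample differential expression on a log2 matrix
#'
#' Per-feature Welch two-sample t-test (Student optional) on a
#' complete-case, log2-scale matrix. `log2_fold_change` is
#' `mean(groupB) - mean(groupA)` where A and B are the first and second
#' factor levels of `groups`. A feature is called significant when
#' `|log2FC| >= log2(fc_cutoff)` AND `p < p_cutoff` AND `q <= fdr_cutoff`
#' (each gate independently configurable; set a gate to NULL to drop it).
#' Features constant in both groups get p = 1 with a warning when the group
#' means are equal.
#'
#' @param se `SummarizedExperiment` tagged `log2`, complete cases.
#' @param groups factor/character of length `ncol(se)` with exactly 2 levels.
#' @param fc_cutoff fold-change gate on the raw scale (default 2).
#' @param p_cutoff raw p-value gate (default 0.05).
#' @param fdr_cutoff BH q-value gate (default 0.05).
#' @param var_equal Student instead of Welch (default FALSE).
#' @return list with `results` (feature, log2_fold_change, p_value, q_value,
#'   direction) and `summary` (up/down/ns counts and printed-precision
#'   percentages among significant features).
#' @export
twoSampleDE <- function(se, groups, fc_cutoff = 2, p_cutoff = 0.05,
                        fdr_cutoff = 0.05, var_equal = FALSE) {
  if (!identical(S4Vectors::metadata(se)$scale, "log2")) {
    stop("twoSampleDE expects a log2-scale matrix")
  }
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two group labels required")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  m <- SummarizedExperiment::assay(se, "abundance")
  if (anyNA(m)) stop("matrix contains missing values; apply completeCaseFilter first")
  a <- m[, groups == levels(groups)[1], drop = FALSE]
  b <- m[, groups == levels(groups)[2], drop = FALSE]
  lfc <- rowMeans(b) - rowMeans(a)
  degenerate <- FALSE
  pv <- vapply(seq_len(nrow(m)), function(i) {
    if (sd(a[i, ]) == 0 && sd(b[i, ]) == 0) {
      degenerate <<- TRUE
      return(if (lfc[i] == 0) 1 else 0)
    }
    t.test(a[i, ], b[i, ], var.equal = var_equal)$p.value
  }, numeric(1))
  if (degenerate) warning("zero-variance feature(s): p set to 1 (equal means) or 0")
  qv <- bhAdjust(pv)
  sig <- rep(TRUE, length(pv))
  if (!is.null(fc_cutoff)) sig <- sig & abs(lfc) >= log2(fc_cutoff)
  if (!is.null(p_cutoff)) sig <- sig & pv < p_cutoff
  if (!is.null(fdr_cutoff)) sig <- sig & qv <= fdr_cutoff
  direction <- ifelse(!sig, "ns", ifelse(lfc > 0, "up", "down"))
  res <- data.frame(feature = rownames(m), log2_fold_change = lfc,
                    p_value = pv, q_value = qv, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  n_up <- sum(direction == "up"); n_down <- sum(direction == "down")
  n_sig <- n_up + n_down
  summary <- data.frame(
    direction = c("down", "up"), count = c(n_down, n_up),
    percent = if (n_sig > 0) c(percentOf(n_down, n_sig), percentOf(n_up, n_sig))
              else c(NA_real_, NA_real_),
    stringsAsFactors = FALSE)
  list(results = res, summary = summary, n_significant = n_sig,
       n_features = nrow(m))
}
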