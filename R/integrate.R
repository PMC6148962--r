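#' Spearman rank correlation with pairwise-complete handling
#'
#' Pearson correlation of mid-ranks over the pairwise-complete observations.
#' Fewer than 3 complete pairs or a constant vector yields NA with a
#' warning.
#'
#' @param x,y numeric vectors of equal length.
#' @return Spearman's rho, or NA.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) {
    warning("fewer than 3 complete pairs; rho undefined")
    return(NA_real_)
  }
  if (length(unique(x[ok])) == 1 || length(unique(y[ok])) == 1) {
    warning("constant vector; rho undefined")
    return(NA_real_)
  }
  cor(x[ok], y[ok], method = "spearman")
}

#' Summarize copy-number segments to gene level
#'
#' For every gene and sample, the length-weighted mean of the copy-number
#' values of the segments overlapping the gene (weights = overlap width in
#' bases); alternatively the value of the single segment with the largest
#' overlap. Genes with no overlapping segment in a sample are NA and listed
#' in the `absent` attribute.
#'
#' @param segments data.frame from [readSegments()].
#' @param annotation data.frame from [readAnnotation()].
#' @param method `"weighted"` (default) or `"max_overlap"`.
#' @return gene x sample numeric matrix with attribute `absent`.
#' @export
geneLevelCnv <- function(segments, annotation,
                         method = c("weighted", "max_overlap")) {
  method <- match.arg(method)
  shared <- intersect(unique(segments$chromosome),
                      unique(annotation$chromosome))
  if (!length(shared)) {
    stop("no shared chromosome naming between segments (",
         paste(unique(segments$chromosome), collapse = ","),
         ") and annotation (",
         paste(unique(annotation$chromosome), collapse = ","), ")")
  }
  genes <- GenomicRanges::GRanges(annotation$chromosome,
                                  IRanges::IRanges(annotation$start,
                                                   annotation$end))
  samples <- unique(segments$sample)
  out <- matrix(NA_real_, nrow = nrow(annotation), ncol = length(samples),
                dimnames = list(annotation$gene, samples))
  for (s in samples) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    gr <- GenomicRanges::GRanges(seg$chromosome,
                                 IRanges::IRanges(seg$start, seg$end))
    ov <- GenomicRanges::findOverlaps(genes, gr)
    if (!length(ov)) next
    w <- BiocGenerics::width(GenomicRanges::pintersect(
      genes[S4Vectors::queryHits(ov)], gr[S4Vectors::subjectHits(ov)]))
    v <- seg$value[S4Vectors::subjectHits(ov)]
    q <- S4Vectors::queryHits(ov)
    if (method == "weighted") {
      num <- tapply(w * v, q, sum)
      den <- tapply(w, q, sum)
      out[as.integer(names(num)), s] <- num / den
    } else {
      for (g in unique(q)) {
        sel <- which(q == g)
        out[g, s] <- v[sel[which.max(w[sel])]]
      }
    }
  }
  attr(out, "absent") <- rownames(out)[rowSums(!is.na(out)) == 0]
  out
}

#' Per-gene Spearman correlation across CNV, mRNA and protein layers
#'
#' For every gene shared between a layer pair, computes Spearman's rho over
#' the shared samples; the reported layer mean is the arithmetic mean of the
#' per-gene rhos over genes with at least `min_samples` complete pairs. A
#' per-gene significance flag (two-sided correlation test, BH-adjusted) is
#' attached for downstream concordance filtering.
#'
#' @param cnv gene x sample matrix (from [geneLevelCnv()]).
#' @param mrna,protein `SummarizedExperiment`s with an `abundance` assay.
#' @param min_samples minimum complete pairs per gene (default 5).
#' @param sig_alpha BH-adjusted significance level (default 0.05).
#' @return list with `per_gene` (gene, rho and adjusted p per layer pair)
#'   and `means` (mean rho per pair).
#' @export
correlateLayers <- function(cnv, mrna, protein, min_samples = 5,
                            sig_alpha = 0.05) {
  mm <- SummarizedExperiment::assay(mrna, "abundance")
  pm <- SummarizedExperiment::assay(protein, "abundance")
  genes <- Reduce(intersect, list(rownames(cnv), rownames(mm), rownames(pm)))
  if (!length(genes)) stop("empty gene intersection across layers")
  pairRho <- function(a, b) {
    samp <- intersect(colnames(a), colnames(b))
    if (length(samp) < 3) stop("fewer than 3 shared samples between layers")
    t(vapply(genes, function(g) {
      x <- a[g, samp]; y <- b[g, samp]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < max(3, min_samples) ||
          length(unique(x[ok])) == 1 || length(unique(y[ok])) == 1) {
        return(c(NA_real_, NA_real_, 0))
      }
      ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                      exact = FALSE))
      c(unname(ct$estimate), ct$p.value, sum(ok))
    }, numeric(3)))
  }
  mp <- pairRho(mm, pm)
  cp <- pairRho(cnv, pm)
  cm <- pairRho(cnv, mm)
  adj <- function(p) { q <- rep(NA_real_, length(p)); ok <- !is.na(p)
                       q[ok] <- bhAdjust(p[ok]); q }
  per_gene <- data.frame(
    gene = genes,
    rho_mrna_protein = mp[, 1], q_mrna_protein = adj(mp[, 2]),
    rho_cnv_protein = cp[, 1], q_cnv_protein = adj(cp[, 2]),
    rho_cnv_mrna = cm[, 1], q_cnv_mrna = adj(cm[, 2]),
    row.names = NULL, stringsAsFactors = FALSE)
  per_gene$sig_mrna_protein <- !is.na(per_gene$q_mrna_protein) &
    per_gene$q_mrna_protein < sig_alpha & per_gene$rho_mrna_protein > 0
  means <- c(mrna_protein = mean(mp[, 1], na.rm = TRUE),
             cnv_protein = mean(cp[, 1], na.rm = TRUE),
             cnv_mrna = mean(cm[, 1], na.rm = TRUE))
  list(per_gene = per_gene, means = means)
}

#' Concordant differential-expression and copy-number sets
#'
#' Nested set intersections: genes differentially expressed at both mRNA and
#' protein level (optionally requiring the same direction), then the subset
#' also carrying a copy-number change. Chromosome tallies of the triple set
#' are ranked descending, ties broken by chromosome label order
#' (1..22, X, Y).
#'
#' @param de_protein,de_mrna `results` data.frames from [twoSampleDE()].
#' @param cnv_changed character vector of copy-number-changed genes, or a
#'   data.frame with columns gene and direction ("up"/"down") for
#'   direction-aware intersection.
#' @param annotation optional gene annotation for the chromosome tally.
#' @param direction_consistent require matching direction (default TRUE).
#' @return list with `mrna_protein` (character), `triple` (character) and
#'   `tally` (data.frame chromosome/n, ranked) when annotation is given.
#' @export
concordantSets <- function(de_protein, de_mrna, cnv_changed,
                           annotation = NULL, direction_consistent = TRUE) {
  sigP <- de_protein[de_protein$direction != "ns", , drop = FALSE]
  sigM <- de_mrna[de_mrna$direction != "ns", , drop = FALSE]
  if (direction_consistent) {
    keyP <- paste(sigP$feature, sigP$direction)
    keyM <- paste(sigM$feature, sigM$direction)
    both <- sigP$feature[keyP %in% keyM]
  } else {
    both <- intersect(sigP$feature, sigM$feature)
  }
  both <- sort(unique(both))
  if (is.data.frame(cnv_changed)) {
    if (direction_consistent) {
      keyC <- paste(cnv_changed$gene, cnv_changed$direction)
      keyB <- paste(sigP$feature, sigP$direction)
      cnv_ok <- cnv_changed$gene[keyC %in% keyB]
    } else cnv_ok <- cnv_changed$gene
  } else cnv_ok <- cnv_changed
  triple <- sort(intersect(both, cnv_ok))
  tally <- NULL
  if (!is.null(annotation) && length(triple)) {
    chr <- annotation$chromosome[match(triple, annotation$gene)]
    tab <- table(factor(chr, levels = CHROM_LABELS))
    tab <- tab[tab > 0]
    ord <- order(-as.integer(tab), match(names(tab), CHROM_LABELS))
    tally <- data.frame(chromosome = names(tab)[ord],
                        n = as.integer(tab)[ord], stringsAsFactors = FALSE)
  }
  list(mrna_protein = both, triple = triple, tally = tally)
}
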