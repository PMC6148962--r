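#' Match observed peptides against a SAAV database
#'
#' Exact string matching (optionally I/L-folded, following the database's own
#' flag) between each sample's identified peptides and the database's mutant
#' sequences. Multiple supporting peptides for the same (sample, site) pair
#' collapse to one observation; peptide-level multiplicity is kept in the
#' `detail` table.
#'
#' @param ids peptide-identification data.frame with columns sample, cohort,
#'   peptide and optional intensity.
#' @param db a [SaavDb-class].
#' @return list with `observations` (one row per sample x site: sample,
#'   cohort, accession, position, ref, alt, site, span_id, intensity) and
#'   `detail` (one row per supporting peptide match).
#' @export
matchPeptides <- function(ids, db) {
  stopIfMissingCols(ids, c("sample", "cohort", "peptide"), "peptide-id table")
  if (is.null(ids$intensity)) ids$intensity <- NA_real_
  if (any(ids$intensity < 0, na.rm = TRUE)) stop("negative intensity")
  if (any(nchar(ids$peptide) < saavParams(db)$min_len)) {
    stop("peptide shorter than the identification minimum length")
  }
  p <- saavPeptides(db)
  dbkey <- p[!duplicated(paste(p$mutant_sequence, p$span_id, p$site)),
             c("mutant_sequence", "span_id", "accession", "position",
               "ref", "alt", "site"), drop = FALSE]
  obs_pep <- ids$peptide
  db_pep <- dbkey$mutant_sequence
  if (isTRUE(saavParams(db)$il_fold)) {
    obs_pep <- foldIL(obs_pep); db_pep <- foldIL(db_pep)
  }
  hit <- match(obs_pep, db_pep)
  detail <- cbind(ids[!is.na(hit), c("sample", "cohort", "peptide",
                                     "intensity"), drop = FALSE],
                  dbkey[hit[!is.na(hit)], c("span_id", "accession",
                                            "position", "ref", "alt",
                                            "site"), drop = FALSE])
  rownames(detail) <- NULL
  key <- paste(detail$sample, detail$accession, detail$site)
  obs <- detail[!duplicated(key), c("sample", "cohort", "accession",
                                    "position", "ref", "alt", "site",
                                    "span_id"), drop = FALSE]
  obs$intensity <- vapply(split(detail$intensity, key)[unique(key)],
                          function(v) suppressWarnings(max(v)), numeric(1))
  obs$intensity[!is.finite(obs$intensity)] <- NA_real_
  rownames(obs) <- NULL
  list(observations = obs, detail = detail)
}

#' Count mutated and total peptides per sample
#'
#' For each sample, the number of distinct identified peptides and how many
#' of them match the SAAV database (mutant sequences).
#'
#' @inheritParams matchPeptides
#' @return data.frame with columns sample, cohort, mutated_count,
#'   total_count.
#' @export
countMutatedPeptides <- function(ids, db) {
  stopIfMissingCols(ids, c("sample", "cohort", "peptide"), "peptide-id table")
  p <- saavPeptides(db)
  db_pep <- unique(p$mutant_sequence)
  pep <- ids$peptide
  if (isTRUE(saavParams(db)$il_fold)) {
    pep <- foldIL(pep); db_pep <- foldIL(db_pep)
  }
  ids$.folded <- pep
  per <- lapply(split(ids, ids$sample), function(d) {
    u <- unique(d$.folded)
    data.frame(sample = d$sample[1], cohort = d$cohort[1],
               mutated_count = sum(u %in% db_pep), total_count = length(u),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  out
}

#' Classify cohort specificity of SAAV sites
#'
#' A site is specific to a cohort when it is observed in at least one sample
#' of that cohort and in no sample of the other; it is shared when observed
#' in both. Adjacent-normal (`exclude`, default "PN") observations are
#' tracked but excluded from the contrast. Per-protein counts follow the
#' occurrence semantics of published SAAV tables: the number of
#' (sample, site) observations attributed to the protein within the class,
#' not the number of distinct sites.
#'
#' @param observations data.frame with columns sample, cohort, accession,
#'   site (e.g. from [matchPeptides()] or an expanded fixture).
#' @param cohorts the two cohort labels to contrast (default c("NM", "MT")).
#' @param exclude cohort labels tracked but left out of the contrast.
#' @return list with `events` (accession, site, class), `per_protein`
#'   (class, accession, n_saavs), and `totals` (named vector over
#'   NM-specific/MT-specific/shared style labels).
#' @export
classifySpecificity <- function(observations, cohorts = c("NM", "MT"),
                                exclude = "PN") {
  stopIfMissingCols(observations, c("sample", "cohort", "accession", "site"),
                    "observation table")
  if (length(cohorts) != 2) stop("exactly two contrast cohorts required")
  unknown <- setdiff(unique(observations$cohort), c(cohorts, exclude))
  if (length(unknown)) {
    stop("unknown cohort label(s): ", paste(unknown, collapse = ", "))
  }
  obs <- observations[observations$cohort %in% cohorts, , drop = FALSE]
  # deduplicate at (sample, site) level
  obs <- obs[!duplicated(paste(obs$sample, obs$accession, obs$site)), ,
             drop = FALSE]
  labA <- paste0(cohorts[1], "-specific")
  labB <- paste0(cohorts[2], "-specific")
  evkey <- paste(obs$accession, obs$site, sep = "|")
  inA <- tapply(obs$cohort == cohorts[1], evkey, any)
  inB <- tapply(obs$cohort == cohorts[2], evkey, any)
  cls <- ifelse(inA & inB, "shared", ifelse(inA, labA, labB))
  ev <- do.call(rbind, strsplit(names(cls), "|", fixed = TRUE))
  events <- data.frame(accession = ev[, 1], site = ev[, 2],
                       class = unname(cls), stringsAsFactors = FALSE)
  obs$class <- cls[match(evkey, names(cls))]
  agg <- stats::aggregate(list(n_saavs = obs$sample),
                          by = list(class = obs$class,
                                    accession = obs$accession), FUN = length)
  agg <- agg[order(agg$class, -agg$n_saavs, agg$accession), , drop = FALSE]
  rownames(agg) <- NULL
  totals <- setNames(numeric(3), c(labA, labB, "shared"))
  tt <- tapply(agg$n_saavs, agg$class, sum)
  totals[names(tt)] <- tt
  list(events = events, per_protein = agg, totals = totals)
}

#' Compare per-sample counts between groups
#'
#' Rank-based comparison of count distributions: two-sided Wilcoxon rank-sum
#' for two groups, Kruskal-Wallis for three or more (ties mid-ranked,
#' normal / chi-square approximation with tie correction). With
#' `exact = TRUE` and two small untied groups, the exact permutation
#' distribution is used instead.
#'
#' @param counts numeric vector of per-sample counts.
#' @param groups group label per sample (2 or more levels).
#' @param exact use the exact two-group distribution when possible.
#' @return list with `statistic`, `p_value`, `method`.
#' @export
compareCounts <- function(counts, groups, exact = FALSE) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("each group needs at least two values")
  if (length(unique(counts)) == 1) {
    warning("all values identical; p set to 1")
    return(list(statistic = 0, p_value = 1, method = "degenerate"))
  }
  if (nlevels(groups) == 2) {
    lv <- levels(groups)
    w <- suppressWarnings(
      wilcox.test(counts[groups == lv[1]], counts[groups == lv[2]],
                  exact = exact, correct = !exact))
    list(statistic = unname(w$statistic), p_value = w$p.value,
         method = "wilcoxon rank-sum")
  } else {
    k <- kruskal.test(counts, groups)
    list(statistic = unname(k$statistic), p_value = k$p.value,
         method = "kruskal-wallis")
  }
}
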