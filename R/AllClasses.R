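#' SaavDb: a variant-peptide database
#'
#' Holds the variant (mutant) tryptic peptides generated by applying
#' single-amino-acid substitutions to a wild-type proteome and re-digesting,
#' after removal of peptides that collide with the wild-type peptide universe.
#' Each row of `peptides` is one surviving variant peptide observation source:
#' span identifier `ACC_start_end`, wild and mutant sequences, the substitution
#' site, and sample/cohort provenance.
#'
#' @slot peptides data.frame with columns span_id, accession, start, end,
#'   missed, wild_sequence, mutant_sequence, position, ref, alt, site,
#'   sample, cohort, span_changed.
#' @slot params list of digestion/build parameters (max_missed, min_len,
#'   proline_rule, il_fold).
#' @slot n_proteins number of proteins in the source proteome.
#' @exportClass SaavDb
setClass("SaavDb",
  representation(peptides = "data.frame", params = "list",
                 n_proteins = "integer"))

setValidity("SaavDb", function(object) {
  req <- c("span_id", "accession", "start", "end", "missed", "wild_sequence",
           "mutant_sequence", "position", "ref", "alt", "site", "sample",
           "cohort", "span_changed")
  miss <- setdiff(req, names(object@peptides))
  if (length(miss)) {
    return(sprintf("peptides lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  p <- object@peptides
  if (nrow(p)) {
    if (any(p$position < p$start | p$position > p$end)) {
      return("event position outside peptide span")
    }
    if (any(p$mutant_sequence == p$wild_sequence)) {
      return("mutant peptide identical to its wild-type pairing")
    }
    if (any(p$span_id != sprintf("%s_%d_%d", p$accession, p$start, p$end))) {
      return("span_id must be formatted ACC_start_end")
    }
  }
  TRUE
})

#' @describeIn SaavDb compact display
#' @param object a `SaavDb`.
#' @export
setMethod("show", "SaavDb", function(object) {
  p <- object@peptides
  cat("SaavDb with", nrow(p), "variant peptide record(s) from",
      length(unique(p$accession)), "protein(s)\n")
  cat("  distinct sites:", length(unique(paste(p$accession, p$site))), "\n")
  cat("  params: max_missed =", object@params$max_missed,
      "| min_len =", object@params$min_len,
      "| proline_rule =", object@params$proline_rule,
      "| il_fold =", object@params$il_fold, "\n")
})

#' Accessors for SaavDb
#'
#' `saavPeptides()` returns the variant-peptide table; `saavParams()` the
#' build parameters.
#'
#' @param x a `SaavDb`.
#' @return a data.frame (`saavPeptides`) or list (`saavParams`).
#' @export
saavPeptides <- function(x) {
  stopifnot(is(x, "SaavDb"))
  x@peptides
}

#' @rdname saavPeptides
#' @export
saavParams <- function(x) {
  stopifnot(is(x, "SaavDb"))
  x@params
}

#' KmCurve: a Kaplan-Meier product-limit curve
#'
#' Step-function survival estimate: at each distinct observed time, the number
#' at risk, number of events, and the running survival probability.
#'
#' @slot time ordered distinct observed times.
#' @slot n_risk number at risk just before each time.
#' @slot n_event number of events at each time.
#' @slot surv product-limit survival estimate after each time.
#' @exportClass KmCurve
setClass("KmCurve",
  representation(time = "numeric", n_risk = "numeric",
                 n_event = "numeric", surv = "numeric"))

setValidity("KmCurve", function(object) {
  s <- object@surv
  if (length(s) != length(object@time)) return("slot lengths differ")
  if (length(s)) {
    if (any(s < 0 | s > 1)) return("survival probabilities outside [0,1]")
    if (any(diff(s) > 1e-12)) return("survival must be non-increasing")
  }
  TRUE
})

#' @describeIn KmCurve compact display
#' @param object a `KmCurve`.
#' @export
setMethod("show", "KmCurve", function(object) {
  cat("KmCurve over", length(object@time), "time point(s);",
      sum(object@n_event), "event(s)\n")
  if (length(object@time)) {
    df <- kmTable(object)
    print(utils::head(df, 8))
    if (nrow(df) > 8) cat("...\n")
  }
})

#' Kaplan-Meier curve as a data.frame
#'
#' @param x a `KmCurve`.
#' @return data.frame with columns time, n_risk, n_event, surv.
#' @export
kmTable <- function(x) {
  stopifnot(is(x, "KmCurve"))
  data.frame(time = x@time, n_risk = x@n_risk, n_event = x@n_event,
             surv = x@surv)
}
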