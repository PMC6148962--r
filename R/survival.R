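#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] and returns a [KmCurve-class]. Times with
#' censoring only do not drop the curve.
#'
#' @param records data.frame with columns time (>= 0) and event (0/1), as
#'   from [readSurvival()].
#' @return a `KmCurve`.
#' @export
kmEstimate <- function(records) {
  stopIfMissingCols(records, c("time", "event"), "survival records")
  if (!nrow(records)) stop("no survival records")
  if (any(records$time < 0)) stop("negative follow-up time")
  if (any(!records$event %in% c(0, 1))) stop("event flag must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  new("KmCurve", time = fit$time, n_risk = fit$n.risk,
      n_event = fit$n.event, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Mantel-Haenszel log-rank comparison of two survival distributions:
#' chi-square with 1 df, two-sided p. With no events at all the test is
#' undefined and p = 1 is returned with a warning. Wraps
#' [survival::survdiff()].
#'
#' @param a,b survival data.frames (columns time, event).
#' @return list with `chi_square`, `p_value`, `n_events`.
#' @export
logrankTest <- function(a, b) {
  for (d in list(a, b)) stopIfMissingCols(d, c("time", "event"), "records")
  if (!nrow(a) || !nrow(b)) stop("both groups must be non-empty")
  dat <- rbind(data.frame(time = a$time, event = a$event, grp = "a"),
               data.frame(time = b$time, event = b$event, grp = "b"))
  if (sum(dat$event) == 0) {
    warning("zero events in both groups; log-rank undefined, p = 1")
    return(list(chi_square = 0, p_value = 1, n_events = 0L))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = dat)
  list(chi_square = unname(sd$chisq),
       p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n_events = as.integer(sum(dat$event)))
}

#' Median-split survival stratification
#'
#' Splits samples into high (strictly above the median of `expression`) and
#' low (at or below: ties go to the low group, deterministically) and runs
#' the log-rank test between the two strata. The grouping is invariant under
#' monotone transforms of the expression values.
#'
#' @param expression named numeric vector of per-sample abundance.
#' @param records survival data.frame with a `sample` column matching
#'   `names(expression)`.
#' @return list with `groups` (records plus a `stratum` column), `cutpoint`,
#'   and `logrank` ([logrankTest()] output).
#' @export
medianSplit <- function(expression, records) {
  stopIfMissingCols(records, c("sample", "time", "event"), "records")
  if (is.null(names(expression))) stop("expression must be named by sample")
  shared <- intersect(names(expression), records$sample)
  if (length(shared) < 4) stop("need at least 4 shared samples")
  ex <- expression[shared]
  if (length(unique(ex)) == 1) {
    stop("all expression values identical; no split possible")
  }
  cut <- median(ex)
  stratum <- ifelse(ex > cut, "high", "low")
  rec <- records[match(shared, records$sample), , drop = FALSE]
  rec$stratum <- stratum
  lr <- logrankTest(rec[rec$stratum == "high", , drop = FALSE],
                    rec[rec$stratum == "low", , drop = FALSE])
  list(groups = rec, cutpoint = cut, logrank = lr)
}
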