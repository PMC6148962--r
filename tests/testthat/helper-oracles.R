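# Independent oracles used across the suite. These deliberately re-derive
# results from first principles (position-by-position scans, enumeration,
# direct formulas) rather than calling the implementation paths they check.

# brute-force tryptic digestion: test every (start, end) substring against
# the cleavage predicate
bruteDigest <- function(sequence, max_missed = 2, min_len = 7,
                        proline_rule = TRUE) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  cleavable <- vapply(seq_len(n), function(i) {
    ch[i] %in% c("K", "R") && (!proline_rule || i == n || ch[i + 1] != "P")
  }, logical(1))
  out <- list()
  for (s in seq_len(n)) {
    if (!(s == 1 || cleavable[s - 1])) next
    for (e in s:n) {
      if (!(e == n || cleavable[e])) next
      if (e - s + 1 < min_len) next
      internal <- if (e > s) sum(cleavable[s:(e - 1)]) else 0
      if (internal > max_missed) next
      out[[length(out) + 1]] <- data.frame(
        start = s, end = e, missed = internal,
        sequence = substr(sequence, s, e), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), missed = integer(),
                      sequence = character()))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end), , drop = FALSE]
}

# random protein over the canonical alphabet
randomProtein <- function(len, kr_weight = 0.07) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  w <- rep((1 - kr_weight) / 18, 20)
  names(w) <- aa
  w["K"] <- w["R"] <- kr_weight / 2
  paste(sample(aa, len, replace = TRUE, prob = w), collapse = "")
}

# exact two-sided rank-sum p-value by enumerating all label assignments
wilcoxEnumP <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(n, nx)
  ws <- apply(idx, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  ple <- mean(ws <= wObs); pge <- mean(ws >= wObs)
  min(1, 2 * min(ple, pge))
}

# log-rank chi-square from the direct O-E / hypergeometric-variance formula
logrankDirect <- function(a, b) {
  dat <- rbind(cbind(a[, c("time", "event")], grp = 1),
               cbind(b[, c("time", "event")], grp = 2))
  tms <- sort(unique(dat$time[dat$event == 1]))
  O <- E <- V <- 0
  for (t in tms) {
    at_risk <- dat$time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & dat$grp == 1)
    d <- sum(dat$time == t & dat$event == 1)
    d1 <- sum(dat$time == t & dat$event == 1 & dat$grp == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# small deterministic proteome fixture: two proteins with known tryptic
# structure (spans worked out by hand in the digestion tests)
toyProteome <- function() {
  c(PROT1 = "MAGVKLLTESTPEPKAAADDDEEERGGGK",
    PROT2 = "MFFFFFFKAAAAAAARCCCCCCC")
}
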