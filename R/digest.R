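#' In-silico tryptic digestion
#'
#' Cleaves a protein C-terminal of K or R, suppressing cleavage when the next
#' residue is proline (`proline_rule = TRUE`, classic trypsin; turn off for
#' the Trypsin/P dialect), and enumerates every peptide retaining up to
#' `max_missed` internal cleavage sites with length at least `min_len`.
#' Protein termini count as cleavage boundaries. Optionally the initiator
#' methionine can be clipped before digestion.
#'
#' @param sequence amino-acid string (or a single named element of an
#'   `AAStringSet`).
#' @param accession parent protein id used in the output; defaults to the
#'   sequence's name.
#' @param max_missed maximum internal retained K/R sites (default 2).
#' @param min_len minimum peptide length reported (default 7 residues).
#' @param proline_rule suppress cleavage before proline (default TRUE).
#' @param clip_met drop a leading methionine before digesting (default FALSE).
#' @return data.frame with columns accession, start, end, missed, sequence,
#'   ordered by start then end. Coordinates are 1-based inclusive in the
#'   (unclipped) parent.
#' @examples
#' digestProtein("MKAAAAAAR", min_len = 1)
#' @export
digestProtein <- function(sequence, accession = NULL, max_missed = 2L,
                          min_len = 7L, proline_rule = TRUE,
                          clip_met = FALSE) {
  if (!is.character(sequence)) sequence <- as.character(sequence)
  if (is.null(accession)) {
    accession <- if (!is.null(names(sequence))) names(sequence)[1] else NA_character_
  }
  sequence <- unname(sequence[1])
  stopifnot(max_missed >= 0, min_len >= 1, nzchar(sequence))
  offset <- 0L
  if (clip_met && substr(sequence, 1, 1) == "M" && nchar(sequence) > 1) {
    sequence <- substr(sequence, 2, nchar(sequence))
    offset <- 1L
  }
  n <- nchar(sequence)
  ch <- strsplit(sequence, "")[[1]]
  # cleavage after position i: K/R at i, and not P at i+1 under the rule
  cut <- which(ch %in% c("K", "R"))
  if (proline_rule) cut <- cut[cut == n | ch[pmin(cut + 1L, n)] != "P"]
  bounds <- unique(c(0L, cut[cut < n], n))   # fragment boundaries
  frag_start <- bounds[-length(bounds)] + 1L
  frag_end <- bounds[-1]
  k <- length(frag_start)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    jmax <- min(k, i + max_missed)
    j <- i:jmax
    rows[[i]] <- data.frame(start = frag_start[i], end = frag_end[j],
                            missed = j - i)
  }
  out <- do.call(rbind, rows)
  out <- out[out$end - out$start + 1L >= min_len, , drop = FALSE]
  if (!nrow(out)) {
    return(data.frame(accession = character(), start = integer(),
                      end = integer(), missed = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  data.frame(accession = accession,
             start = out$start + offset, end = out$end + offset,
             missed = out$missed,
             sequence = substring(sequence, out$start, out$end),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tryptic peptides covering a residue position
#'
#' The subset of [digestProtein()] output whose span contains `position`
#' (1-based). Used to find which peptides can evidence a substitution site.
#'
#' @inheritParams digestProtein
#' @param position 1-based residue index in the parent protein.
#' @return data.frame in [digestProtein()] layout.
#' @export
peptidesAt <- function(sequence, position, accession = NULL, max_missed = 2L,
                       min_len = 7L, proline_rule = TRUE) {
  if (!is.character(sequence)) sequence <- as.character(sequence)
  if (position < 1 || position > nchar(sequence[1])) {
    stop(sprintf("position %d outside protein of length %d", position,
                 nchar(sequence[1])))
  }
  peps <- digestProtein(sequence, accession = accession,
                        max_missed = max_missed, min_len = min_len,
                        proline_rule = proline_rule)
  peps[peps$start <= position & position <= peps$end, , drop = FALSE]
}

#' Digest every protein of a proteome
#'
#' @param proteome named `AAStringSet` or named character vector.
#' @inheritParams digestProtein
#' @return one data.frame of peptides over all proteins.
#' @export
digestProteome <- function(proteome, max_missed = 2L, min_len = 7L,
                           proline_rule = TRUE) {
  seqs <- if (is.character(proteome)) proteome else
    setNames(as.character(proteome), names(proteome))
  out <- lapply(names(seqs), function(acc) {
    digestProtein(seqs[[acc]], accession = acc, max_missed = max_missed,
                  min_len = min_len, proline_rule = proline_rule)
  })
  do.call(rbind, out)
}
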