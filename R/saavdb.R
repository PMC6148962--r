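#' Apply a single-amino-acid substitution to a protein
#'
#' Replaces the residue at `position` with `alt` after checking that the
#' protein actually carries `ref` there; a mismatch signals a stale variant
#' annotation and is an error.
#'
#' @param sequence protein amino-acid string.
#' @param position 1-based residue index.
#' @param ref expected reference residue.
#' @param alt substituted residue (must differ from `ref`).
#' @return the mutated sequence (same length).
#' @examples
#' applyEvent("AAADAAA", 4, "D", "N")  # "AAANAAA"
#' @export
applyEvent <- function(sequence, position, ref, alt) {
  if (!is.character(sequence)) sequence <- as.character(sequence)
  sequence <- unname(sequence[1])
  if (ref == alt) stop("substitution with ref == alt")
  if (position < 1 || position > nchar(sequence)) {
    stop(sprintf("position %d outside protein of length %d", position,
                 nchar(sequence)))
  }
  have <- substr(sequence, position, position)
  if (have != ref) {
    stop(sprintf("reference mismatch at position %d: expected %s, found %s",
                 position, ref, have))
  }
  substr(sequence, position, position) <- alt
  sequence
}

#' Variant tryptic peptides for one substitution
#'
#' Applies the substitution, re-digests the *mutated* sequence, and keeps the
#' peptides whose span contains the substituted position. Each is paired with
#' the wild-type peptide of identical span from the unmutated digest when one
#' exists; when the substitution creates or destroys a K/R cleavage site the
#' mutant spans have no wild counterpart, and the pairing falls back to the
#' shortest wild peptide covering the position with `span_changed = TRUE`.
#'
#' @inheritParams applyEvent
#' @param accession parent protein id.
#' @inheritParams digestProtein
#' @return data.frame with columns span_id, accession, start, end, missed,
#'   wild_sequence, mutant_sequence, position, ref, alt, site, span_changed.
#' @export
variantPeptides <- function(sequence, position, ref, alt, accession,
                            max_missed = 2L, min_len = 7L,
                            proline_rule = TRUE) {
  if (!is.character(sequence)) sequence <- as.character(sequence)
  sequence <- unname(sequence[1])
  mut <- applyEvent(sequence, position, ref, alt)
  mpep <- digestProtein(mut, accession = accession, max_missed = max_missed,
                        min_len = min_len, proline_rule = proline_rule)
  mpep <- mpep[mpep$start <= position & position <= mpep$end, , drop = FALSE]
  if (!nrow(mpep)) return(emptyVariantPeptides())
  wpep <- digestProtein(sequence, accession = accession,
                        max_missed = max_missed, min_len = 1L,
                        proline_rule = proline_rule)
  wkey <- paste(wpep$start, wpep$end)
  wild <- character(nrow(mpep)); changed <- logical(nrow(mpep))
  for (i in seq_len(nrow(mpep))) {
    hit <- match(paste(mpep$start[i], mpep$end[i]), wkey)
    if (!is.na(hit)) {
      wild[i] <- wpep$sequence[hit]
      changed[i] <- FALSE
    } else {
      cover <- wpep[wpep$start <= position & position <= wpep$end, , drop = FALSE]
      cover <- cover[order(cover$end - cover$start), , drop = FALSE]
      wild[i] <- if (nrow(cover)) cover$sequence[1] else NA_character_
      changed[i] <- TRUE
    }
  }
  data.frame(span_id = sprintf("%s_%d_%d", accession, mpep$start, mpep$end),
             accession = accession, start = mpep$start, end = mpep$end,
             missed = mpep$missed, wild_sequence = wild,
             mutant_sequence = mpep$sequence, position = position,
             ref = ref, alt = alt, site = formatSite(ref, position, alt),
             span_changed = changed, row.names = NULL,
             stringsAsFactors = FALSE)
}

emptyVariantPeptides <- function() {
  data.frame(span_id = character(), accession = character(),
             start = integer(), end = integer(), missed = integer(),
             wild_sequence = character(), mutant_sequence = character(),
             position = integer(), ref = character(), alt = character(),
             site = character(), span_changed = logical(),
             stringsAsFactors = FALSE)
}

#' Locate the substitution between a wild/mutant peptide pair
#'
#' Given equal-length wild-type and mutant peptide strings differing at
#' exactly one residue and the 1-based protein coordinate where the peptide
#' starts, returns the protein coordinate of the substitution and the
#' exchanged residues: `position = start + offset - 1` where `offset` is the
#' 1-based index of the differing residue within the peptide.
#'
#' @param wild wild-type peptide string.
#' @param mutant mutant peptide string (same length).
#' @param start 1-based protein coordinate of the peptide's first residue.
#' @return list with `position`, `ref`, `alt`.
#' @examples
#' substitutionSite("IQEGVFDIDNEANGIK", "IQEGVFDINNEANGIK", 171)
#' # position 179, ref "D", alt "N"
#' @export
substitutionSite <- function(wild, mutant, start) {
  if (nchar(wild) != nchar(mutant)) {
    stop("wild and mutant peptides have unequal lengths")
  }
  w <- strsplit(wild, "")[[1]]
  m <- strsplit(mutant, "")[[1]]
  diff <- which(w != m)
  if (length(diff) == 0) stop("peptides are identical: no substitution")
  if (length(diff) > 1) {
    stop("peptides differ at ", length(diff), " positions; expected exactly 1")
  }
  list(position = as.integer(start + diff - 1L), ref = w[diff], alt = m[diff])
}

#' Remove variant peptides indistinguishable from wild-type peptides
#'
#' A mutant peptide only evidences a substitution if its sequence occurs
#' nowhere in the wild-type peptide universe. With `il_fold = TRUE` the
#' comparison is done after mapping isoleucine to leucine on both sides,
#' since the two are isobaric and indistinguishable by mass spectrometry.
#'
#' @param candidates data.frame from [variantPeptides()].
#' @param wild_universe character vector of all wild-type peptides of the
#'   proteome (same digestion parameters).
#' @param il_fold fold I to L before comparing (default FALSE).
#' @return the surviving subset of `candidates`.
#' @export
filterWildtypeCollisions <- function(candidates, wild_universe,
                                     il_fold = FALSE) {
  if (!nrow(candidates)) return(candidates)
  mut <- candidates$mutant_sequence
  uni <- unique(wild_universe)
  if (il_fold) { mut <- foldIL(mut); uni <- foldIL(uni) }
  candidates[!mut %in% uni, , drop = FALSE]
}

#' Build a customized SAAV peptide database
#'
#' For every substitution event, applies it to its protein, re-digests the
#' mutated sequence, keeps peptides covering the substituted residue, and
#' removes candidates colliding with any wild-type peptide of the proteome.
#' Events whose reference residue does not match the proteome are collected
#' and reported together as an error (stale-annotation guard), unless
#' `on_mismatch = "warn"` drops them with a warning.
#'
#' @param proteome named `AAStringSet` or named character vector.
#' @param events data.frame as from [readVariantTable()] (accession,
#'   position, ref, alt, site, sample, cohort).
#' @param max_missed,min_len,proline_rule digestion parameters (defaults 2,
#'   7, TRUE).
#' @param il_fold fold I/L in the collision filter and later matching.
#' @param on_mismatch `"error"` (default) or `"warn"`.
#' @return a [SaavDb-class] object.
#' @export
buildSaavDb <- function(proteome, events, max_missed = 2L, min_len = 7L,
                        proline_rule = TRUE, il_fold = FALSE,
                        on_mismatch = c("error", "warn")) {
  on_mismatch <- match.arg(on_mismatch)
  seqs <- if (is.character(proteome)) proteome else
    setNames(as.character(proteome), names(proteome))
  need <- c("accession", "position", "ref", "alt", "sample", "cohort")
  stopIfMissingCols(events, need, "event table")
  bad <- !events$accession %in% names(seqs)
  if (any(bad)) {
    stop("event accession(s) absent from proteome: ",
         paste(unique(events$accession[bad]), collapse = ", "))
  }
  mismatch <- character()
  recs <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    res <- tryCatch(
      variantPeptides(seqs[[ev$accession]], ev$position, ev$ref, ev$alt,
                      accession = ev$accession, max_missed = max_missed,
                      min_len = min_len, proline_rule = proline_rule),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      mismatch <- c(mismatch, sprintf("%s %s: %s", ev$accession,
                                      formatSite(ev$ref, ev$position, ev$alt),
                                      res))
      recs[[i]] <- emptyVariantPeptides()
    } else if (nrow(res)) {
      res$sample <- ev$sample
      res$cohort <- ev$cohort
      recs[[i]] <- res
    } else {
      recs[[i]] <- res
    }
  }
  if (length(mismatch)) {
    msg <- paste0("reference-mismatch report (", length(mismatch),
                  " event(s)):\n  ", paste(mismatch, collapse = "\n  "))
    if (on_mismatch == "error") stop(msg) else warning(msg)
  }
  cand <- do.call(rbind, recs[vapply(recs, nrow, integer(1)) > 0])
  if (is.null(cand)) {
    cand <- emptyVariantPeptides()
    cand$sample <- character(); cand$cohort <- character()
  }
  wild <- digestProteome(seqs, max_missed = max_missed, min_len = min_len,
                         proline_rule = proline_rule)
  kept <- filterWildtypeCollisions(cand, wild$sequence, il_fold = il_fold)
  kept <- kept[order(kept$accession, kept$start, kept$end, kept$site,
                     kept$sample), , drop = FALSE]
  rownames(kept) <- NULL
  new("SaavDb",
      peptides = kept[, c("span_id", "accession", "start", "end", "missed",
                          "wild_sequence", "mutant_sequence", "position",
                          "ref", "alt", "site", "sample", "cohort",
                          "span_changed")],
      params = list(max_missed = max_missed, min_len = min_len,
                    proline_rule = proline_rule, il_fold = il_fold),
      n_proteins = length(seqs))
}

#' Write a SAAV database as FASTA plus index table
#'
#' One FASTA record per distinct variant peptide with header
#' `ACC_start_end|XnY`; the companion TSV index keeps one row per
#' (span, site, sample, cohort) provenance entry. Record order is
#' deterministic (accession, start, end, site).
#'
#' @param db a [SaavDb-class].
#' @param fasta_path output FASTA path.
#' @param index_path output TSV path.
#' @return invisibly, a list with the two paths.
#' @export
writeSaavFasta <- function(db, fasta_path, index_path) {
  p <- saavPeptides(db)
  key <- paste(p$span_id, p$site)
  uni <- p[!duplicated(key), , drop = FALSE]
  seqs <- Biostrings::AAStringSet(setNames(uni$mutant_sequence,
                                           paste0(uni$span_id, "|", uni$site)))
  Biostrings::writeXStringSet(seqs, fasta_path)
  idx <- p[, c("span_id", "site", "accession", "start", "end",
               "mutant_sequence", "wild_sequence", "sample", "cohort",
               "span_changed")]
  write.table(idx, index_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta_path, index = index_path))
}
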