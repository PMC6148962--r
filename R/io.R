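#' Read a wild-type proteome from FASTA
#'
#' Loads protein records into an [Biostrings::AAStringSet]. The accession is
#' the header token before the first whitespace; with
#' `dialect = "uniprot"` headers of the form `sp|ACC|NAME` are reduced to
#' `ACC`. Sequences must use the 20 canonical amino-acid letters unless
#' `allow_extended` admits U/B/Z/X.
#'
#' @param path FASTA file.
#' @param dialect `"token"` (default) or `"uniprot"`.
#' @param allow_extended allow U/B/Z/X letters (default FALSE: error).
#' @return an `AAStringSet` named by accession; `mcols()$gene` carries gene
#'   symbols when headers contain `GN=<symbol>`.
#' @export
readProteomeFasta <- function(path, dialect = c("token", "uniprot"),
                              allow_extended = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  acc <- sub("\\s.*$", "", headers)
  if (dialect == "uniprot") {
    hit <- grepl("^(sp|tr)\\|[^|]+\\|", acc)
    acc[hit] <- sub("^(sp|tr)\\|([^|]+)\\|.*$", "\\2", acc[hit])
  }
  dup <- acc[duplicated(acc)]
  if (length(dup)) {
    stop("duplicate accession(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  if (any(Biostrings::width(aa) == 0)) stop("empty sequence in FASTA")
  seqs <- setNames(as.character(aa), acc)
  checkCanonicalAA(seqs, allow_extended = allow_extended, what = path)
  names(aa) <- acc
  gene <- ifelse(grepl("GN=", headers), sub(".*GN=(\\S+).*", "\\1", headers),
                 NA_character_)
  S4Vectors::mcols(aa)$gene <- gene
  aa
}

#' Write a proteome to FASTA
#'
#' @param proteome named `AAStringSet` (or named character vector).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProteomeFasta <- function(proteome, path) {
  if (is.character(proteome)) proteome <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(proteome, path)
  invisible(path)
}

#' Parse and format compact substitution-site notation
#'
#' `"D179N"` means reference residue D at 1-based position 179 substituted by
#' N. `parseSite()` returns the components; `formatSite()` is its inverse, so
#' parsing then formatting reproduces the input string exactly.
#'
#' @param site character vector like `"D179N"`.
#' @return `parseSite`: data.frame with columns ref, position, alt.
#' @examples
#' parseSite("D179N")             # ref D, position 179, alt N
#' formatSite("D", 179, "N")      # "D179N"
#' @export
parseSite <- function(site) {
  ok <- grepl("^[A-Z][0-9]+[A-Z]$", site)
  if (any(!ok)) stop("malformed site notation: ", paste(site[!ok], collapse = ", "))
  ref <- substr(site, 1, 1)
  alt <- substr(site, nchar(site), nchar(site))
  pos <- as.integer(substr(site, 2, nchar(site) - 1))
  if (any(pos < 1)) stop("non-positive site position")
  if (any(ref == alt)) stop("site with identical ref and alt: ",
                            paste(site[ref == alt], collapse = ", "))
  data.frame(ref = ref, position = pos, alt = alt)
}

#' @rdname parseSite
#' @param ref,alt single amino-acid letters.
#' @param position 1-based residue position.
#' @export
formatSite <- function(ref, position, alt) sprintf("%s%d%s", ref, position, alt)

#' Read a protein-level somatic variant table
#'
#' TSV with columns `accession`, `sample`, `cohort` and either a compact
#' `site` column (`"D179N"`) or the triple `ref`, `position`, `alt`.
#'
#' @param path TSV file.
#' @return data.frame of events with columns accession, position, ref, alt,
#'   site, sample, cohort.
#' @export
readVariantTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopIfMissingCols(df, c("accession", "sample", "cohort"), path)
  if ("site" %in% names(df)) {
    parts <- parseSite(df$site)
    df$ref <- parts$ref; df$position <- parts$position; df$alt <- parts$alt
  } else {
    stopIfMissingCols(df, c("position", "ref", "alt"), path)
    df$position <- as.integer(df$position)
    if (any(df$position < 1)) stop("non-positive variant position in ", path)
    if (any(df$ref == df$alt)) stop("variant with ref == alt in ", path)
    df$site <- formatSite(df$ref, df$position, df$alt)
  }
  checkCanonicalAA(setNames(paste0(df$ref, df$alt), df$accession),
                   what = "variant ref/alt letters")
  df[, c("accession", "position", "ref", "alt", "site", "sample", "cohort")]
}

#' @rdname readVariantTable
#' @param events event data.frame as returned by `readVariantTable`.
#' @export
writeVariantTable <- function(events, path) {
  out <- events[, c("accession", "site", "sample", "cohort")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a feature-by-sample quantification matrix
#'
#' TSV with the feature id in the first column and one column per sample.
#' Empty cells are missing values; `"NA"`/`"NaN"` are accepted as missing
#' under `lenient_na = TRUE` (the default), otherwise they are an error.
#' Returns a [SummarizedExperiment::SummarizedExperiment] with a single
#' `abundance` assay; `metadata()$scale` records whether values are `raw` or
#' already `log2`.
#'
#' @param path TSV file.
#' @param scale `"raw"` or `"log2"` tag recorded in the object metadata.
#' @param lenient_na treat "NA"/"NaN" strings as missing.
#' @return a `SummarizedExperiment`.
#' @export
readQuantMatrix <- function(path, scale = c("raw", "log2"), lenient_na = TRUE) {
  scale <- match.arg(scale)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character", na.strings = NULL)
  if (ncol(df) < 2) stop("quant matrix needs a feature column plus samples")
  feat <- df[[1]]
  if (anyDuplicated(feat)) {
    stop("duplicated feature id(s): ",
         paste(unique(feat[duplicated(feat)]), collapse = ", "))
  }
  cells <- as.matrix(df[, -1, drop = FALSE])
  cells[cells == ""] <- NA
  if (lenient_na) cells[cells %in% c("NA", "NaN")] <- NA
  else if (any(cells %in% c("NA", "NaN"))) {
    stop("non-numeric cell in ", path, " (set lenient_na = TRUE to accept)")
  }
  suppressWarnings(vals <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- !is.na(cells) & is.na(vals)
  if (any(bad)) stop("non-numeric cell value(s) in ", path)
  dimnames(vals) <- list(feat, colnames(df)[-1])
  if (scale == "raw" && any(vals < 0, na.rm = TRUE)) {
    stop("negative values in a matrix tagged raw")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = vals))
  S4Vectors::metadata(se)$scale <- scale
  se
}

#' @rdname readQuantMatrix
#' @param se a `SummarizedExperiment` with an `abundance` assay.
#' @param feature_col header for the feature-id column.
#' @export
writeQuantMatrix <- function(se, path, feature_col = "feature") {
  m <- SummarizedExperiment::assay(se, "abundance")
  fmt <- matrix(vapply(m, function(v) {
    if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1)), nrow = nrow(m), dimnames = dimnames(m))
  df <- data.frame(rownames(m), fmt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(feature_col, colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write SEG-style copy-number segments
#'
#' TSV with columns sample, chromosome, start, end, value; coordinates are
#' 1-based inclusive.
#'
#' @param path SEG-style TSV.
#' @return data.frame of segments, input order preserved.
#' @export
readSegments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopIfMissingCols(df, c("sample", "chromosome", "start", "end", "value"), path)
  df$chromosome <- as.character(df$chromosome)
  if (any(df$start > df$end)) stop("segment with start > end in ", path)
  if (any(!nzchar(df$sample))) stop("empty sample id in ", path)
  if (any(is.na(df$value))) stop("missing segment value in ", path)
  df
}

#' @rdname readSegments
#' @param segments segment data.frame.
#' @export
writeSegments <- function(segments, path) {
  out <- segments[, c("sample", "chromosome", "start", "end", "value")]
  out$value <- format(out$value, digits = 15, scientific = FALSE, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write survival records
#'
#' TSV with columns sample, time (follow-up, months), event (1 = event,
#' 0 = censored) and optional group.
#'
#' @param path TSV file.
#' @return data.frame with columns sample, time, event, group.
#' @export
readSurvival <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopIfMissingCols(df, c("sample", "time", "event"), path)
  if (any(df$time < 0)) stop("negative follow-up time in ", path)
  if (any(!df$event %in% c(0, 1))) stop("event flag must be 0/1 in ", path)
  if (is.null(df$group)) df$group <- NA_character_
  df[, c("sample", "time", "event", "group")]
}

#' @rdname readSurvival
#' @param records survival data.frame.
#' @export
writeSurvival <- function(records, path) {
  write.table(records[, c("sample", "time", "event", "group")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' TSV with columns gene, chromosome, start, end (1-based inclusive) and
#' optional band.
#'
#' @param path TSV file.
#' @return data.frame of gene coordinates.
#' @export
readAnnotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopIfMissingCols(df, c("gene", "chromosome", "start", "end"), path)
  df$chromosome <- as.character(df$chromosome)
  bad <- !df$chromosome %in% CHROM_LABELS
  if (any(bad)) {
    stop("invalid chromosome label(s): ",
         paste(unique(df$chromosome[bad]), collapse = ", "))
  }
  if (any(df$start > df$end)) stop("annotation with start > end in ", path)
  df
}

#' Validate an input file against its schema
#'
#' Dispatches to the matching reader and reports success or the parse error.
#'
#' @param path file to check.
#' @param format one of `"fasta"`, `"variants"`, `"matrix"`, `"segments"`,
#'   `"survival"`, `"annotation"`.
#' @return TRUE invisibly on success; stops with the reader's error otherwise.
#' @export
validateFile <- function(path, format = c("fasta", "variants", "matrix",
                                          "segments", "survival",
                                          "annotation")) {
  format <- match.arg(format)
  switch(format,
    fasta = readProteomeFasta(path),
    variants = readVariantTable(path),
    matrix = readQuantMatrix(path),
    segments = readSegments(path),
    survival = readSurvival(path),
    annotation = readAnnotation(path))
  invisible(TRUE)
}
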