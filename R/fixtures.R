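#' Load a packaged SAAV table fixture
#'
#' The package ships the published cohort-specificity tables of SAAVs as
#' plain-text fixtures: `"table2"` (NM-specific sites), `"table3"` (sites
#' shared by NM and MT) and `"table4"` (MT-specific sites). Each row holds
#' the protein name, accession, printed wild-type and mutant peptide
#' strings, the `ACC_start_end` span identifier, the compact substitution
#' site (e.g. `D179N`) and the occurrence count (`n_saavs`, occurrences
#' across patients, not distinct sites). Transcription caveats are noted in
#' each file's comment header.
#'
#' @param name one of `"table2"`, `"table3"`, `"table4"`.
#' @return data.frame of fixture rows; columns additionally include parsed
#'   `start`, `end` from the span identifier.
#' @examples
#' nrow(loadFixture("table2"))          # 8 proteins
#' sum(loadFixture("table3")$n_saavs)   # 26 occurrences
#' @export
loadFixture <- function(name = c("table2", "table3", "table4")) {
  name <- match.arg(name)
  file <- c(table2 = "table2_nm_specific.tsv",
            table3 = "table3_shared.tsv",
            table4 = "table4_mt_specific.tsv")[[name]]
  path <- system.file("extdata", file, package = "saavomics", mustWork = TRUE)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  parts <- regmatches(df$span_id,
                      regexec("^(.+)_([0-9]+)_([0-9]+)$", df$span_id))
  df$start <- vapply(parts, function(p) as.integer(p[3]), integer(1))
  df$end <- vapply(parts, function(p) as.integer(p[4]), integer(1))
  df
}

#' Expand table fixtures into per-sample SAAV observations
#'
#' Turns the occurrence counts of the packaged tables into one observation
#' row per (pseudo-sample, site), suitable for [classifySpecificity()]:
#' NM-specific rows produce NM observations, MT-specific rows MT
#' observations, and shared rows alternate NM/MT starting with NM (so every
#' shared site is observed in both cohorts; all shared counts are >= 2).
#'
#' @param tables fixture names to expand (default all three).
#' @return observation data.frame (sample, cohort, accession, site).
#' @export
fixtureObservations <- function(tables = c("table2", "table3", "table4")) {
  cohort_of <- c(table2 = "NM", table3 = "shared", table4 = "MT")
  rows <- lapply(tables, function(tb) {
    df <- loadFixture(tb)
    per <- lapply(seq_len(nrow(df)), function(i) {
      k <- df$n_saavs[i]
      coh <- if (cohort_of[[tb]] == "shared") {
        rep(c("NM", "MT"), length.out = k)
      } else rep(cohort_of[[tb]], k)
      data.frame(sample = sprintf("%s_%s_%02d", coh, df$accession[i],
                                  seq_len(k)),
                 cohort = coh, accession = df$accession[i],
                 site = df$site[i], stringsAsFactors = FALSE)
    })
    do.call(rbind, per)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
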