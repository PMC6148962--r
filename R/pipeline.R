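#' Run the full pipeline on simulated inputs
#'
#' End-to-end orchestration over the synthetic study: generate a proteome
#' and planted substitution events, build the SAAV peptide database,
#' simulate peptide identifications and call SAAVs (per-sample mutated
#' counts, cohort-specificity classes, NM-vs-MT rank test), simulate the
#' copy-number / mRNA / protein cascade and integrate the layers
#' (gene-level CNV, per-gene Spearman correlations), simulate a raw
#' label-free matrix and run normalization plus differential expression,
#' and simulate survival records for a log-rank comparison. When `out_dir`
#' is given, every stage input/output is written there (to a temporary
#' area, moved into place only when the whole run succeeds) together with a
#' `run_log.txt` recording the package version, the full configuration and
#' the seed.
#'
#' @param cfg a [simConfig()] list.
#' @param out_dir optional output directory.
#' @return named list of stage summaries (counts, means, p-values).
#' @export
runPipeline <- function(cfg = simConfig(), out_dir = NULL) {
  proteome <- generateProteome(cfg)
  planted <- plantSaavs(proteome, cfg)
  db <- buildSaavDb(proteome, planted$events)
  ids <- simulatePeptideIds(proteome, db, cfg)
  calls <- matchPeptides(ids, db)
  counts <- countMutatedPeptides(ids, db)
  spec <- classifySpecificity(calls$observations)
  tumor <- counts[counts$cohort %in% c("NM", "MT"), ]
  cmp <- compareCounts(tumor$mutated_count, tumor$cohort)

  annotation <- simulateAnnotation(cfg)
  cascade <- simulateQuantCascade(cfg, annotation)
  cnv <- geneLevelCnv(cascade$segments, annotation)
  layers <- correlateLayers(cnv, cascade$mrna, cascade$protein)

  lfq <- simulateLfqMatrix(cfg)
  norm <- log2MedianNormalize(lfq$se)
  cc <- completeCaseFilter(norm)
  de <- twoSampleDE(cc, SummarizedExperiment::colData(cc)$group)

  surv <- simulateSurvival(cfg)
  km <- kmEstimate(surv)
  lr <- logrankTest(surv[surv$group == surv$group[1], ],
                    surv[surv$group != surv$group[1], ])

  summary <- list(
    seed = cfg$seed,
    saav = list(n_db_records = nrow(saavPeptides(db)),
                n_observations = nrow(calls$observations),
                specificity_totals = spec$totals,
                count_test = cmp),
    integration = list(layer_means = layers$means,
                       n_genes = nrow(layers$per_gene)),
    de = list(n_features = de$n_features, n_significant = de$n_significant,
              summary = de$summary),
    survival = list(n_events = sum(surv$event),
                    logrank_chi_square = lr$chi_square,
                    logrank_p = lr$p_value))

  if (!is.null(out_dir)) {
    tmp <- tempfile("saavomics_run_")
    dir.create(tmp, recursive = TRUE)
    writeProteomeFasta(proteome, file.path(tmp, "proteome.fasta"))
    writeVariantTable(planted$events, file.path(tmp, "variants.tsv"))
    writeSaavFasta(db, file.path(tmp, "saav_db.fasta"),
                   file.path(tmp, "saav_index.tsv"))
    write.table(counts, file.path(tmp, "mutated_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(spec$per_protein, file.path(tmp, "specificity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeSegments(cascade$segments, file.path(tmp, "cnv.seg"))
    writeQuantMatrix(cascade$mrna, file.path(tmp, "mrna.tsv"))
    writeQuantMatrix(cascade$protein, file.path(tmp, "protein.tsv"))
    write.table(layers$per_gene, file.path(tmp, "integration.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(de$results, file.path(tmp, "de_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeSurvival(surv, file.path(tmp, "survival.tsv"))
    write.table(kmTable(km), file.path(tmp, "km_curve.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    log <- c(paste("saavomics version:",
                   as.character(utils::packageVersion("saavomics"))),
             paste("seed:", cfg$seed), "config:",
             paste0("  ", names(cfg), " = ",
                    vapply(cfg, function(v) paste(format(v), collapse = ","),
                           character(1))))
    writeLines(log, file.path(tmp, "run_log.txt"))
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (f in list.files(tmp)) {
      file.copy(file.path(tmp, f), file.path(out_dir, f), overwrite = TRUE)
    }
    unlink(tmp, recursive = TRUE)
  }
  summary
}
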