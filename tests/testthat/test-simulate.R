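test_that("generators are deterministic given the seed", {
  cfg <- simConfig(seed = 77, n_proteins = 5, protein_len_mean = 120,
                   protein_len_sd = 10)
  expect_identical(generateProteome(cfg), generateProteome(cfg))
  p <- generateProteome(cfg)
  expect_identical(plantSaavs(p, cfg), plantSaavs(p, cfg))
  expect_identical(simulateSurvival(cfg), simulateSurvival(cfg))
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeProteomeFasta(p, f1)
  writeProteomeFasta(p, f2)
  expect_identical(readLines(f1), readLines(f2))
  # empty proteome is allowed
  expect_length(generateProteome(simConfig(n_proteins = 0)), 0)
})

test_that("synthetic proteomes have realistic tryptic fragment lengths", {
  cfg <- simConfig(seed = 13, n_proteins = 60, protein_len_mean = 400,
                   protein_len_sd = 60)
  p <- generateProteome(cfg)
  frags <- digestProteome(p, max_missed = 0, min_len = 1)
  expect_lt(abs(mean(nchar(frags$sequence)) - 14), 3)
})

test_that("planted events always pass applyEvent and follow the cohort design", {
  cfg <- simConfig(seed = 14, n_proteins = 10, protein_len_mean = 200,
                   protein_len_sd = 40)
  p <- generateProteome(cfg)
  pl <- plantSaavs(p, cfg)
  for (i in seq_len(nrow(pl$events))) {
    ev <- pl$events[i, ]
    expect_silent(applyEvent(p[[ev$accession]], ev$position, ev$ref, ev$alt))
  }
  # occurrence totals follow the configured design
  expect_equal(nrow(pl$events), sum(cfg$n_events))
  expect_equal(table(pl$truth$class)[["NM-specific"]],
               cfg$n_events[["nm_specific"]])
  # shared sites appear in both cohorts
  shared_sites <- pl$truth$site[pl$truth$class == "shared"]
  for (s in shared_sites) {
    expect_setequal(pl$events$cohort[pl$events$site == s], c("NM", "MT"))
  }
  # zero planted events: empty everything downstream
  cfg0 <- simConfig(seed = 14, n_proteins = 4,
                    n_events = c(nm_specific = 0L, shared = 0L,
                                 mt_specific = 0L))
  pl0 <- plantSaavs(generateProteome(cfg0), cfg0)
  expect_equal(nrow(pl0$events), 0)
})

test_that("peptide identification dropout behaves at its extremes", {
  cfg <- simConfig(seed = 15, n_proteins = 4, protein_len_mean = 100,
                   protein_len_sd = 10, n_nm = 2, n_mt = 2,
                   n_events = c(nm_specific = 2L, shared = 2L,
                                mt_specific = 2L))
  p <- generateProteome(cfg)
  pl <- plantSaavs(p, cfg)
  db <- buildSaavDb(p, pl$events)
  wild <- unique(digestProteome(p)$sequence)
  ids1 <- simulatePeptideIds(p, db, cfg, detect_prob = 1)
  for (s in unique(ids1$sample)) {
    expect_true(all(wild %in% ids1$peptide[ids1$sample == s]))
  }
  # variant peptides occur only in carrier samples
  vp <- saavPeptides(db)
  det <- matchPeptides(ids1, db)$detail
  carried <- unique(paste(vp$sample, vp$site))
  expect_true(all(paste(det$sample, det$site) %in% carried))
  expect_null(simulatePeptideIds(p, db, cfg, detect_prob = 0))
})

test_that("the quant cascade honors its limit cases and rejects absurd targets", {
  expect_error(simulateQuantCascade(simConfig(target_rho_mp = 0.999)),
               "unreachable")
  expect_error(simulateQuantCascade(simConfig(target_rho_mp = 0.3,
                                              target_rho_cp = 0.6)),
               "cannot exceed")
  # independent layers: mean rho near 0
  cfg0 <- simConfig(seed = 16, n_genes = 80, n_cascade_samples = 20,
                    target_rho_mp = 0, target_rho_cp = 0)
  cas0 <- simulateQuantCascade(cfg0)
  rhos <- vapply(seq_len(80), function(g) {
    spearmanRho(SummarizedExperiment::assay(cas0$mrna)[g, ],
                SummarizedExperiment::assay(cas0$protein)[g, ])
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.1)
  # segments reconstruct the latent per-gene values exactly
  cfg <- simConfig(seed = 17, n_genes = 40, n_cascade_samples = 8)
  ann <- simulateAnnotation(cfg)
  cas <- simulateQuantCascade(cfg, ann)
  cnv <- geneLevelCnv(cas$segments, ann)
  seg1 <- cas$segments[cas$segments$sample == "S01", ]
  expect_equal(unname(cnv[, "S01"]), seg1$value)
})

test_that("LFQ simulation plants recoverable fold changes", {
  cfg <- simConfig(seed = 18, n_features = 400, n_per_group = 8,
                   de_fraction = 0.1, de_lfc = 2, missing_rate = 0)
  lfq <- simulateLfqMatrix(cfg)
  norm <- completeCaseFilter(log2MedianNormalize(lfq$se))
  de <- twoSampleDE(norm, SummarizedExperiment::colData(norm)$group)
  called <- de$results$feature[de$results$direction != "ns"]
  # all planted features recovered, nothing spurious beyond the FDR budget
  expect_true(all(lfq$truth$feature %in% called))
  expect_lte(length(setdiff(called, lfq$truth$feature)),
             ceiling(0.1 * length(called)))
  # planted directions match
  dir <- de$results$direction[match(lfq$truth$feature, de$results$feature)]
  expect_equal(dir, lfq$truth$direction)
})

test_that("survival simulation respects censoring and hazard scaling", {
  cfg0 <- simConfig(seed = 19, censor_rate = 0, n_surv_per_group = 50)
  s0 <- simulateSurvival(cfg0)
  expect_true(all(s0$event == 1))
  # median event time scales as 1/hazard
  cfgA <- simConfig(seed = 20, hazard = 0.02, hazard_ratio = 1,
                    censor_rate = 0, n_surv_per_group = 400)
  cfgB <- simConfig(seed = 20, hazard = 0.08, hazard_ratio = 1,
                    censor_rate = 0, n_surv_per_group = 400)
  mA <- median(simulateSurvival(cfgA)$time)
  mB <- median(simulateSurvival(cfgB)$time)
  expect_equal(mA / mB, 4, tolerance = 0.25)
})

test_that("packaged table fixtures load and are internally consistent", {
  t2 <- loadFixture("table2")
  expect_equal(nrow(t2), 8)
  expect_equal(sum(t2$n_saavs), 12)
  t3 <- loadFixture("table3")
  expect_equal(sum(t3$n_saavs), 26)
  expect_equal(nrow(t3), 6)
  t4 <- loadFixture("table4")
  expect_equal(sum(t4$n_saavs), 11)
  expect_error(loadFixture("table9"))
  # every row's printed site position is reproduced from its peptide pair
  for (tb in list(t2, t3, t4)) {
    for (i in seq_len(nrow(tb))) {
      got <- substitutionSite(tb$wild_peptide[i], tb$mutant_peptide[i],
                              tb$start[i])
      expect_equal(got$position, parseSite(tb$site[i])$position)
      expect_equal(got$ref, parseSite(tb$site[i])$ref)
      expect_equal(tb$end[i] - tb$start[i] + 1, nchar(tb$wild_peptide[i]))
    }
  }
})

test_that("the full pipeline runs end to end, deterministically, with atomic outputs", {
  cfg <- simConfig(seed = 23, n_proteins = 6, protein_len_mean = 120,
                   protein_len_sd = 20, n_nm = 4, n_mt = 4,
                   n_events = c(nm_specific = 3L, shared = 4L,
                                mt_specific = 3L),
                   n_genes = 30, n_cascade_samples = 10,
                   n_features = 60, n_per_group = 5, missing_rate = 0,
                   n_surv_per_group = 15)
  out <- withr::local_tempdir()
  s1 <- runPipeline(cfg, out_dir = out)
  s2 <- runPipeline(cfg)
  expect_equal(s1, s2)
  expect_true(all(c("proteome.fasta", "saav_db.fasta", "mutated_counts.tsv",
                    "integration.tsv", "de_results.tsv", "survival.tsv",
                    "run_log.txt") %in% list.files(out)))
  log <- readLines(file.path(out, "run_log.txt"))
  expect_true(any(grepl("seed: 23", log)))
  expect_true(any(grepl("version", log)))
})
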