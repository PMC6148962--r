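toyDbAndIds <- function() {
  parent <- paste0(paste(rep("A", 169), collapse = ""), "K",
                   "IQEGVFDIDNEANGIK",
                   paste(rep("G", 20), collapse = ""))
  proteome <- c(P61019 = parent, OTHER = "MWWWWWWWKCCCCCCCR")
  events <- data.frame(accession = "P61019", position = 179, ref = "D",
                       alt = "N", sample = "NM01", cohort = "NM",
                       stringsAsFactors = FALSE)
  db <- buildSaavDb(proteome, events)
  list(proteome = proteome, db = db)
}

test_that("peptide matching finds mutant peptides and ignores wild ones", {
  x <- toyDbAndIds()
  ids <- data.frame(
    sample = c("NM01", "NM01", "MT01"),
    cohort = c("NM", "NM", "MT"),
    peptide = c("IQEGVFDINNEANGIK", "IQEGVFDIDNEANGIK", "IQEGVFDIDNEANGIK"),
    intensity = c(10, 20, 30), stringsAsFactors = FALSE)
  res <- matchPeptides(ids, x$db)
  expect_equal(nrow(res$observations), 1)
  expect_equal(res$observations$sample, "NM01")
  expect_equal(res$observations$site, "D179N")
  # the wild-only sample contributes no observation
  expect_false("MT01" %in% res$observations$sample)
})

test_that("matching equals brute-force all-pairs comparison on a toy set", {
  cfg <- simConfig(seed = 9, n_proteins = 6, protein_len_mean = 120,
                   protein_len_sd = 20)
  proteome <- generateProteome(cfg)
  planted <- plantSaavs(proteome, cfg)
  db <- buildSaavDb(proteome, planted$events)
  ids <- simulatePeptideIds(proteome, db, cfg, detect_prob = 0.5)
  res <- matchPeptides(ids, db)
  p <- saavPeptides(db)
  brute <- unique(do.call(rbind, lapply(seq_len(nrow(ids)), function(i) {
    hits <- p[p$mutant_sequence == ids$peptide[i], , drop = FALSE]
    if (!nrow(hits)) return(NULL)
    data.frame(sample = ids$sample[i], accession = hits$accession[1],
               site = hits$site[1])
  })))
  got <- unique(res$observations[, c("sample", "accession", "site")])
  expect_equal(nrow(got), nrow(brute))
  expect_setequal(paste(got$sample, got$accession, got$site),
                  paste(brute$sample, brute$accession, brute$site))
})

test_that("mutated-peptide counts match planted truth at full detection", {
  cfg <- simConfig(seed = 4, n_proteins = 8, protein_len_mean = 130,
                   protein_len_sd = 25)
  proteome <- generateProteome(cfg)
  planted <- plantSaavs(proteome, cfg)
  db <- buildSaavDb(proteome, planted$events)
  ids <- simulatePeptideIds(proteome, db, cfg, detect_prob = 1)
  counts <- countMutatedPeptides(ids, db)
  expect_true(all(counts$mutated_count <= counts$total_count))
  p <- saavPeptides(db)
  expected <- vapply(counts$sample, function(s) {
    length(unique(p$mutant_sequence[p$sample == s]))
  }, integer(1))
  expect_equal(counts$mutated_count, unname(expected))
  # removing all variant records zeroes the counts
  db0 <- buildSaavDb(proteome, planted$events[0, ])
  counts0 <- countMutatedPeptides(ids, db0)
  expect_true(all(counts0$mutated_count == 0))
})

test_that("specificity classes partition observed events and recover the planted design", {
  cfg <- simConfig(seed = 6, n_proteins = 10, protein_len_mean = 150,
                   protein_len_sd = 30)
  proteome <- generateProteome(cfg)
  planted <- plantSaavs(proteome, cfg)
  db <- buildSaavDb(proteome, planted$events)
  ids <- simulatePeptideIds(proteome, db, cfg, detect_prob = 1)
  obs <- matchPeptides(ids, db)$observations
  spec <- classifySpecificity(obs)
  # partition property
  expect_equal(nrow(spec$events),
               length(unique(paste(obs$accession, obs$site)[
                 obs$cohort %in% c("NM", "MT")])))
  # planted design recovered exactly for detectable sites
  truthKey <- setNames(planted$truth$class,
                       paste(planted$truth$accession, planted$truth$site))
  gotKey <- setNames(spec$events$class,
                     paste(spec$events$accession, spec$events$site))
  expect_equal(unname(gotKey), unname(truthKey[names(gotKey)]))
  # invariance to row order and duplicated observations
  obs2 <- rbind(obs[sample(nrow(obs)), ], obs[1:3, ])
  expect_equal(classifySpecificity(obs2)$totals, spec$totals)
  # unknown cohort labels are rejected
  obs3 <- obs
  obs3$cohort[1] <- "ZZ"
  expect_error(classifySpecificity(obs3), "unknown cohort")
})

test_that("count comparison matches the permutation oracle and detects shifts", {
  # identical groups: degenerate, p = 1
  expect_warning(res <- compareCounts(rep(3, 8), rep(c("a", "b"), 4)),
                 "identical")
  expect_equal(res$p_value, 1)
  # exact small-sample p equals enumeration over label assignments
  set.seed(31)
  for (i in 1:5) {
    x <- sample(1:100, 4); y <- sample(101:200, 4)  # no ties
    got <- compareCounts(c(x, y), rep(c("a", "b"), each = 4), exact = TRUE)
    expect_equal(got$p_value, wilcoxEnumP(x, y))
  }
  # a large shift is detected at n = 20 per group
  set.seed(32)
  a <- rpois(20, 10); b <- rpois(20, 10) + 15
  expect_lt(compareCounts(c(a, b), rep(c("a", "b"), each = 20))$p_value, 0.05)
  # three groups fall through to Kruskal-Wallis
  res3 <- compareCounts(c(1:4, 2:5, 10:13), rep(c("a", "b", "c"), each = 4))
  expect_equal(res3$method, "kruskal-wallis")
})
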