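test_that("applyEvent substitutes one residue, is an involution, and guards the reference", {
  prot <- "AAADAAAK"
  mut <- applyEvent(prot, 4, "D", "N")
  expect_equal(mut, "AAANAAAK")
  expect_equal(applyEvent(mut, 4, "N", "D"), prot)
  expect_error(applyEvent(prot, 4, "E", "N"), "reference mismatch")
  expect_error(applyEvent(prot, 4, "D", "D"), "ref == alt")
  expect_error(applyEvent(prot, 99, "D", "N"), "outside")
})

test_that("substitutionSite recovers the printed site arithmetic and rejects bad pairs", {
  s <- substitutionSite("IQEGVFDIDNEANGIK", "IQEGVFDINNEANGIK", 171)
  expect_equal(s, list(position = 179L, ref = "D", alt = "N"))
  s <- substitutionSite("AGVIAHIEEER", "AGVITHIEEER", 765)
  expect_equal(s, list(position = 769L, ref = "A", alt = "T"))
  s <- substitutionSite("NAIDDGCVVPGAGAVEVAMAEAIIK",
                        "NAIDDGCVVPGAGAVEVAMAEAINK", 400)
  expect_equal(s, list(position = 423L, ref = "I", alt = "N"))
  expect_error(substitutionSite("AAA", "AAAA", 1), "unequal")
  expect_error(substitutionSite("AAA", "AAA", 1), "identical")
  expect_error(substitutionSite("AAA", "CCA", 1), "2 positions")
})

test_that("substitutionSite is the left inverse of applying a substitution to the wild peptide", {
  set.seed(21)
  for (i in 1:25) {
    wild <- randomProtein(sample(7:25, 1))
    off <- sample(nchar(wild), 1)
    ref <- substr(wild, off, off)
    alt <- sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], ref), 1)
    start <- sample(1:500, 1)
    mut <- wild
    substr(mut, off, off) <- alt
    got <- substitutionSite(wild, mut, start)
    expect_equal(got, list(position = as.integer(start + off - 1), ref = ref,
                           alt = alt))
  }
})

test_that("variantPeptides digests the mutated sequence and pairs wild spans", {
  # RAB2A-like layout: the span 171-186 is tryptic in a synthetic parent
  parent <- paste0(paste(rep("A", 169), collapse = ""), "K",
                   "IQEGVFDIDNEANGIK",
                   paste(rep("G", 20), collapse = ""))
  vp <- variantPeptides(parent, 179, "D", "N", accession = "P61019")
  hit <- vp[vp$start == 171 & vp$end == 186, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$wild_sequence, "IQEGVFDIDNEANGIK")
  expect_equal(hit$mutant_sequence, "IQEGVFDINNEANGIK")
  expect_equal(hit$span_id, "P61019_171_186")
  expect_false(hit$span_changed)
  expect_true(all(vp$start <= 179 & 179 <= vp$end))
})

test_that("substitutions that destroy or create cleavage sites are flagged", {
  # A5 -> K creates a cleavage site: the short mutant span 1-5 has no
  # counterpart in the wild digest
  prot <- "AAAAAAAACCCC"
  vp <- variantPeptides(prot, 5, "A", "K", accession = "P1", min_len = 1)
  created <- vp[vp$start == 1 & vp$end == 5, ]
  expect_true(created$span_changed)
  expect_equal(created$mutant_sequence, "AAAAK")
  expect_equal(created$wild_sequence, prot)  # covering wild peptide
  # K14 -> Q destroys a site: the joined mutant span pairs with the wild
  # missed-cleavage peptide of the same span, so no span change is flagged
  prot2 <- "AAADDDKCCCEEEKGGGHHHK"
  vp2 <- variantPeptides(prot2, 14, "K", "Q", accession = "P2", min_len = 1)
  joined <- vp2[vp2$start == 8 & vp2$end == 21, ]
  expect_equal(joined$wild_sequence[1], "CCCEEEKGGGHHHK")
  expect_false(joined$span_changed[1])
  # event at position 1 of a K/R-free protein: single full-length peptide
  vp2 <- variantPeptides("MAAAAAAA", 1, "M", "V", accession = "P2")
  expect_equal(vp2$mutant_sequence, "VAAAAAAA")
  expect_equal(vp2$span_id, "P2_1_8")
})

test_that("wild-type collision filtering equals a brute-force scan, with I/L folding", {
  set.seed(22)
  proteome <- setNames(vapply(1:20, function(i) randomProtein(60),
                              character(1)),
                       sprintf("T%02d", 1:20))
  wild <- digestProteome(proteome, min_len = 7)$sequence
  # candidates: every single-substitution peptide of one protein's digest
  cand <- variantPeptides(proteome[[1]], 30,
                          substr(proteome[[1]], 30, 30),
                          setdiff(c("L", "V"),
                                  substr(proteome[[1]], 30, 30))[1],
                          accession = "T01")
  kept <- filterWildtypeCollisions(cand, wild)
  brute <- cand[!vapply(cand$mutant_sequence,
                        function(s) any(wild == s), logical(1)), ]
  expect_equal(kept$mutant_sequence, brute$mutant_sequence)
  # I -> L candidates vanish under folding
  prot <- c(P1 = "AAAIAAAKCCCCCCC")
  vpIL <- variantPeptides(prot[[1]], 4, "I", "L", accession = "P1")
  wild1 <- digestProteome(prot, min_len = 7)$sequence
  expect_gt(nrow(filterWildtypeCollisions(vpIL, wild1, il_fold = FALSE)), 0)
  expect_equal(nrow(filterWildtypeCollisions(vpIL, wild1, il_fold = TRUE)), 0)
})

test_that("buildSaavDb emits valid records, reports mismatches, and round-trips to FASTA", {
  proteome <- toyProteome()
  events <- data.frame(
    accession = c("PROT1", "PROT2"), position = c(7, 10),
    ref = c("L", "A"), alt = c("V", "G"),
    sample = c("NM01", "MT01"), cohort = c("NM", "MT"),
    stringsAsFactors = FALSE)
  db <- buildSaavDb(proteome, events, min_len = 5)
  p <- saavPeptides(db)
  expect_true(validObject(db))
  expect_true(all(p$position >= p$start & p$position <= p$end))
  expect_true(all(nchar(p$mutant_sequence) >= 5))
  fa <- withr::local_tempfile(fileext = ".fasta")
  ix <- withr::local_tempfile(fileext = ".tsv")
  writeSaavFasta(db, fa, ix)
  recs <- Biostrings::readAAStringSet(fa)
  expect_true(all(grepl("^.+_[0-9]+_[0-9]+\\|[A-Z][0-9]+[A-Z]$", names(recs))))
  idx <- read.delim(ix, stringsAsFactors = FALSE)
  expect_setequal(idx$cohort, c("NM", "MT"))
  # reference mismatches are aggregated into one report
  bad <- events
  bad$ref <- c("W", "W")
  expect_error(buildSaavDb(proteome, bad), "reference-mismatch report \\(2")
  # zero events give an empty database
  db0 <- buildSaavDb(proteome, events[0, ])
  expect_equal(nrow(saavPeptides(db0)), 0)
})

test_that("planted detectable events are all recovered by the database (100% recall)", {
  cfg <- simConfig(seed = 5, n_proteins = 12, protein_len_mean = 150,
                   protein_len_sd = 30)
  proteome <- generateProteome(cfg)
  planted <- plantSaavs(proteome, cfg)
  db <- buildSaavDb(proteome, planted$events)
  p <- saavPeptides(db)
  covered <- unique(paste(p$accession, p$site))
  # independent oracle for detectability: brute-force digest of the mutated
  # sequence; an event is detectable iff some length>=7 peptide covers the
  # position and does not occur verbatim among wild-type peptides
  wild <- unique(digestProteome(proteome)$sequence)
  truth <- unique(planted$events[, c("accession", "position", "ref", "alt",
                                     "site")])
  detectable <- vapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    mut <- applyEvent(proteome[[tr$accession]], tr$position, tr$ref, tr$alt)
    bd <- bruteDigest(mut, max_missed = 2, min_len = 7)
    bd <- bd[bd$start <= tr$position & tr$position <= bd$end, ]
    any(!bd$sequence %in% wild)
  }, logical(1))
  want <- paste(truth$accession, truth$site)[detectable]
  expect_setequal(covered, want)  # 100% recall of detectable events
  expect_true(all(nchar(p$mutant_sequence) >= 7))
})
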