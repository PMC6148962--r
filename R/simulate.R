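#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with defaults that
#' emulate the study design the package targets: 21 non-metastatic (NM) and
#' 23 liver-metastatic (MT) patients with paired adjacent-normal (PN)
#' tissue; 12 NM-specific, 26 shared and 11 MT-specific planted substitution
#' occurrences; a copy-number to mRNA to protein cascade calibrated to mean
#' Spearman correlations of 0.53 (mRNA-protein) and 0.41 (CNV-protein) over
#' 150 genes and 30 samples; label-free matrices of 2000 features with a 10%
#' differentially expressed fraction at 2-fold; and exponential survival
#' with a hazard ratio of 3.
#'
#' @param seed master random seed (recorded in every output).
#' @param n_proteins number of synthetic proteins.
#' @param protein_len_mean,protein_len_sd,protein_len_min normal length model.
#' @param n_nm,n_mt tumor sample counts per cohort.
#' @param n_events named counts of planted substitution occurrences per
#'   specificity class (nm_specific / mt_specific / shared).
#' @param detect_prob peptide detection probability per sample (dropout
#'   model).
#' @param n_genes,n_cascade_samples cascade dimensions.
#' @param target_rho_mp,target_rho_cp cascade mean Spearman targets
#'   (mRNA-protein, CNV-protein).
#' @param n_features,n_per_group,de_fraction,de_lfc,missing_rate label-free
#'   matrix model (de_lfc on the log2 scale).
#' @param hazard,hazard_ratio,censor_rate,n_surv_per_group survival model
#'   (exponential event times, months).
#' @return a list of class `saav_sim_config`.
#' @export
simConfig <- function(seed = 1L,
                      n_proteins = 30L, protein_len_mean = 300,
                      protein_len_sd = 80, protein_len_min = 60L,
                      n_nm = 21L, n_mt = 23L,
                      n_events = c(nm_specific = 12L, shared = 26L,
                                   mt_specific = 11L),
                      detect_prob = 0.8,
                      n_genes = 150L, n_cascade_samples = 30L,
                      target_rho_mp = 0.53, target_rho_cp = 0.41,
                      n_features = 2000L, n_per_group = 10L,
                      de_fraction = 0.1, de_lfc = 2, missing_rate = 0.1,
                      hazard = 0.02, hazard_ratio = 3, censor_rate = 0.3,
                      n_surv_per_group = 30L) {
  cfg <- as.list(environment())
  stopifnot(cfg$detect_prob >= 0, cfg$detect_prob <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate <= 1,
            cfg$censor_rate >= 0, cfg$censor_rate <= 1,
            cfg$hazard_ratio > 0, cfg$n_proteins >= 0)
  class(cfg) <- "saav_sim_config"
  cfg
}

# amino-acid sampling weights: K+R mass ~1/14 so tryptic fragments average
# ~14 residues under the proline rule
aaWeights <- function() {
  w <- setNames(rep(NA_real_, 20), AA_CANONICAL)
  w["K"] <- w["R"] <- 1 / 28
  w["P"] <- 0.047
  rest <- setdiff(AA_CANONICAL, c("K", "R", "P"))
  w[rest] <- (1 - sum(w, na.rm = TRUE)) / length(rest)
  w
}

#' Generate a synthetic proteome
#'
#' Random amino-acid sequences with lysine/arginine frequency tuned so the
#' mean fully-cleaved tryptic fragment length is about 14 residues.
#' Deterministic given the config seed.
#'
#' @param cfg a [simConfig()] list.
#' @return named character vector of protein sequences (accessions
#'   `SP0001`, ...).
#' @export
generateProteome <- function(cfg) {
  set.seed(cfg$seed)
  if (cfg$n_proteins == 0) return(setNames(character(), character()))
  w <- aaWeights()
  lens <- pmax(cfg$protein_len_min,
               round(rnorm(cfg$n_proteins, cfg$protein_len_mean,
                           cfg$protein_len_sd)))
  seqs <- vapply(lens, function(L) {
    paste(sample(names(w), L, replace = TRUE, prob = w), collapse = "")
  }, character(1))
  setNames(seqs, sprintf("SP%04d", seq_len(cfg$n_proteins)))
}

simSampleSheet <- function(cfg) {
  data.frame(
    sample = c(sprintf("NM%02d", seq_len(cfg$n_nm)),
               sprintf("MT%02d", seq_len(cfg$n_mt)),
               sprintf("PN%02d", seq_len(cfg$n_nm + cfg$n_mt))),
    cohort = c(rep("NM", cfg$n_nm), rep("MT", cfg$n_mt),
               rep("PN", cfg$n_nm + cfg$n_mt)),
    stringsAsFactors = FALSE)
}

#' Plant substitution events with known cohort design
#'
#' Samples distinct (protein, position) sites, takes the reference residue
#' from the sequence, draws a different alternate residue, and assigns each
#' occurrence to carrier samples according to the configured class design:
#' NM-specific and MT-specific events get carriers from one cohort only,
#' shared events from both. One table row = one occurrence (sample, event).
#'
#' @param proteome named character vector from [generateProteome()].
#' @param cfg a [simConfig()] list.
#' @return list with `events` (variant-table data.frame: accession,
#'   position, ref, alt, site, sample, cohort) and `truth` (per distinct
#'   site: accession, site, class).
#' @export
plantSaavs <- function(proteome, cfg) {
  set.seed(cfg$seed + 1L)
  sheet <- simSampleSheet(cfg)
  nm <- sheet$sample[sheet$cohort == "NM"]
  mt <- sheet$sample[sheet$cohort == "MT"]
  ne <- cfg$n_events
  # distinct sites: one per nm/mt-specific occurrence set; shared sites carry
  # 2 occurrences each (one NM + one MT)
  n_shared_sites <- ceiling(ne[["shared"]] / 2)
  n_sites <- ne[["nm_specific"]] + ne[["mt_specific"]] + n_shared_sites
  if (n_sites == 0) {
    empty <- data.frame(accession = character(), position = integer(),
                        ref = character(), alt = character(),
                        site = character(), sample = character(),
                        cohort = character(), stringsAsFactors = FALSE)
    return(list(events = empty,
                truth = data.frame(accession = character(), site = character(),
                                   class = character())))
  }
  acc <- sample(names(proteome), n_sites, replace = TRUE)
  pos <- vapply(acc, function(a) sample.int(nchar(proteome[[a]]), 1L),
                integer(1))
  key <- paste(acc, pos)
  while (anyDuplicated(key)) {
    d <- which(duplicated(key))
    pos[d] <- vapply(acc[d], function(a) sample.int(nchar(proteome[[a]]), 1L),
                     integer(1))
    key <- paste(acc, pos)
  }
  ref <- substring(proteome[acc], pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(AA_CANONICAL, r), 1L),
                character(1))
  cls <- c(rep("NM-specific", ne[["nm_specific"]]),
           rep("MT-specific", ne[["mt_specific"]]),
           rep("shared", n_shared_sites))
  truth <- data.frame(accession = acc, position = as.integer(pos), ref = ref,
                      alt = alt, site = formatSite(ref, as.integer(pos), alt),
                      class = cls, row.names = NULL, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    carriers <- switch(tr$class,
      "NM-specific" = data.frame(sample = sample(nm, 1L), cohort = "NM"),
      "MT-specific" = data.frame(sample = sample(mt, 1L), cohort = "MT"),
      shared = data.frame(sample = c(sample(nm, 1L), sample(mt, 1L)),
                          cohort = c("NM", "MT")))
    data.frame(accession = tr$accession, position = tr$position,
               ref = tr$ref, alt = tr$alt, site = tr$site,
               sample = carriers$sample, cohort = carriers$cohort,
               stringsAsFactors = FALSE)
  })
  events <- do.call(rbind, rows)
  # trim one shared occurrence if the shared count was odd
  n_excess <- nrow(events) - sum(ne)
  if (n_excess > 0) {
    drop <- utils::tail(which(events$cohort == "MT" &
      events$site %in% truth$site[truth$class == "shared"]), n_excess)
    events <- events[-drop, , drop = FALSE]
    demoted <- setdiff(truth$site[truth$class == "shared"], character())
    still_shared <- events$site[duplicated(events$site)]
    truth$class[truth$class == "shared" &
                !truth$site %in% still_shared] <- "NM-specific"
  }
  rownames(events) <- NULL
  list(events = events,
       truth = truth[, c("accession", "site", "class")])
}

#' Simulate per-sample peptide identifications
#'
#' Every distinct wild-type tryptic peptide of the proteome is observed in
#' each sample with probability `detect_prob`; a variant (mutant) peptide is
#' observable only in the samples that carry its event, again with
#' probability `detect_prob`. Intensities are log-normal.
#'
#' @param proteome named character vector.
#' @param db [SaavDb-class] built from the planted events.
#' @param cfg a [simConfig()] list.
#' @param detect_prob overrides `cfg$detect_prob` when given.
#' @return peptide-identification data.frame (sample, cohort, peptide,
#'   intensity).
#' @export
simulatePeptideIds <- function(proteome, db, cfg, detect_prob = NULL) {
  set.seed(cfg$seed + 2L)
  if (is.null(detect_prob)) detect_prob <- cfg$detect_prob
  pars <- saavParams(db)
  wild <- unique(digestProteome(proteome, max_missed = pars$max_missed,
                                min_len = pars$min_len,
                                proline_rule = pars$proline_rule)$sequence)
  sheet <- simSampleSheet(cfg)
  vp <- saavPeptides(db)
  rows <- lapply(seq_len(nrow(sheet)), function(i) {
    s <- sheet$sample[i]
    seen <- wild[runif(length(wild)) < detect_prob]
    mut <- unique(vp$mutant_sequence[vp$sample == s])
    mut <- mut[runif(length(mut)) < detect_prob]
    pep <- c(seen, mut)
    if (!length(pep)) return(NULL)
    data.frame(sample = s, cohort = sheet$cohort[i], peptide = pep,
               intensity = rlnorm(length(pep), meanlog = 20, sdlog = 1.5),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic gene annotation
#'
#' `n_genes` non-overlapping genes laid out round-robin across chromosomes
#' 1..22 and X.
#'
#' @param cfg a [simConfig()] list.
#' @return annotation data.frame (gene, chromosome, start, end).
#' @export
simulateAnnotation <- function(cfg) {
  chroms <- c(as.character(1:22), "X")
  g <- seq_len(cfg$n_genes)
  chr <- chroms[((g - 1) %% length(chroms)) + 1]
  slot <- (g - 1) %/% length(chroms)
  start <- slot * 100000L + 1L
  data.frame(gene = sprintf("G%04d", g), chromosome = chr,
             start = start, end = start + 49999L, stringsAsFactors = FALSE)
}

# achieved mean per-gene Spearman for the two-noise cascade, measured with
# the same estimator and sample count used downstream (per-gene rho over
# n_samp samples, averaged over calibration genes)
cascadeRho <- function(s1, s2, seed, n_samp, n_genes = 200L) {
  set.seed(seed)
  cn <- matrix(rnorm(n_genes * n_samp), n_genes, n_samp)
  mr <- cn + matrix(rnorm(n_genes * n_samp, sd = s1), n_genes, n_samp)
  pr <- mr + matrix(rnorm(n_genes * n_samp, sd = s2), n_genes, n_samp)
  mp <- vapply(seq_len(n_genes),
               function(g) cor(mr[g, ], pr[g, ], method = "spearman"),
               numeric(1))
  cp <- vapply(seq_len(n_genes),
               function(g) cor(cn[g, ], pr[g, ], method = "spearman"),
               numeric(1))
  c(mp = mean(mp), cp = mean(cp))
}

bisect <- function(f, lo, hi, iters = 12L) {
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate the CNV - mRNA - protein cascade
#'
#' Gene-wise latent copy number feeds mRNA through additive noise, and mRNA
#' feeds protein through further (attenuating) noise. The two noise scales
#' are calibrated by nested bisection against the achieved Spearman
#' correlation on a large fixed-seed draw, so the generated data hit the
#' configured mean rank correlations (defaults 0.53 mRNA-protein, 0.41
#' CNV-protein). Copy number is emitted as one SEG segment per gene and
#' sample over the annotation coordinates.
#'
#' @param cfg a [simConfig()] list; targets above 0.99 are rejected.
#' @param annotation gene annotation (default [simulateAnnotation()]).
#' @return list with `segments` (SEG data.frame), `mrna` and `protein`
#'   (`SummarizedExperiment`s tagged log2), and `truth` (noise SDs and
#'   calibration correlations).
#' @export
simulateQuantCascade <- function(cfg, annotation = simulateAnnotation(cfg)) {
  if (cfg$target_rho_mp > 0.99 || cfg$target_rho_cp > 0.99) {
    stop("correlation targets above 0.99 are unreachable")
  }
  if (cfg$target_rho_cp > cfg$target_rho_mp) {
    stop("the induced CNV-protein correlation cannot exceed mRNA-protein")
  }
  cal_seed <- cfg$seed + 3L
  n_samp <- cfg$n_cascade_samples
  zero <- cfg$target_rho_mp <= 0
  if (zero) {
    s1 <- s2 <- 1  # placeholders; protein is drawn independently below
  } else {
    inner <- function(s1) {
      bisect(function(s2) cascadeRho(s1, s2, cal_seed, n_samp)[["mp"]] -
               cfg$target_rho_mp, lo = 1e-3, hi = 50)
    }
    s1 <- if (cfg$target_rho_cp <= 0) 50 else
      bisect(function(s1) cascadeRho(s1, inner(s1), cal_seed,
                                     n_samp)[["cp"]] -
               cfg$target_rho_cp, lo = 1e-3, hi = 50, iters = 10L)
    s2 <- inner(s1)
  }
  ach <- cascadeRho(s1, s2, cal_seed, n_samp)
  set.seed(cfg$seed + 4L)
  n_g <- cfg$n_genes; n_s <- cfg$n_cascade_samples
  samples <- sprintf("S%02d", seq_len(n_s))
  genes <- annotation$gene[seq_len(min(n_g, nrow(annotation)))]
  n_g <- length(genes)
  cn <- matrix(rnorm(n_g * n_s), n_g, n_s, dimnames = list(genes, samples))
  mr <- cn + matrix(rnorm(n_g * n_s, sd = s1), n_g, n_s)
  pr <- if (zero) matrix(rnorm(n_g * n_s), n_g, n_s) else
    mr + matrix(rnorm(n_g * n_s, sd = s2), n_g, n_s)
  dimnames(mr) <- dimnames(pr) <- dimnames(cn)
  ann <- annotation[match(genes, annotation$gene), ]
  segments <- data.frame(
    sample = rep(samples, each = n_g),
    chromosome = rep(ann$chromosome, n_s),
    start = rep(ann$start, n_s), end = rep(ann$end, n_s),
    value = as.vector(cn), stringsAsFactors = FALSE)
  asSe <- function(m) {
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(abundance = m))
    S4Vectors::metadata(se)$scale <- "log2"
    S4Vectors::metadata(se)$seed <- cfg$seed
    se
  }
  list(segments = segments, mrna = asSe(mr), protein = asSe(pr),
       truth = list(noise_sd = c(cnv_mrna = s1, mrna_protein = s2),
                    calibration_rho = ach))
}

#' Simulate a raw label-free quantification matrix
#'
#' Log-normal intensities for `n_features` features over two groups of
#' `n_per_group` samples; a `de_fraction` of features carries a planted
#' log2 shift of `de_lfc` in the second group (alternating sign), and cells
#' are set missing at `missing_rate`. The output is raw-scale, ready for
#' [log2MedianNormalize()].
#'
#' @param cfg a [simConfig()] list.
#' @param groups two group labels (default PN, MT).
#' @return list with `se` (raw `SummarizedExperiment`, `colData()$group`
#'   set) and `truth` (de features and their direction).
#' @export
simulateLfqMatrix <- function(cfg, groups = c("PN", "MT")) {
  set.seed(cfg$seed + 5L)
  n_f <- cfg$n_features; n_s <- 2L * cfg$n_per_group
  feat <- sprintf("F%05d", seq_len(n_f))
  grp <- rep(groups, each = cfg$n_per_group)
  samp <- sprintf("%s%02d", grp, c(seq_len(cfg$n_per_group),
                                   seq_len(cfg$n_per_group)))
  base <- rnorm(n_f, mean = 25, sd = 2)       # log2 baselines
  lm2 <- matrix(rnorm(n_f * n_s, sd = 0.5), n_f, n_s) + base
  n_de <- round(cfg$de_fraction * n_f)
  de_idx <- if (n_de > 0) sample.int(n_f, n_de) else integer()
  sign_up <- rep(c(1, -1), length.out = n_de)
  if (n_de > 0) {
    lm2[de_idx, grp == groups[2]] <- lm2[de_idx, grp == groups[2]] +
      sign_up * cfg$de_lfc
  }
  raw <- 2^lm2
  if (cfg$missing_rate > 0) {
    raw[runif(length(raw)) < cfg$missing_rate] <- NA
  }
  dimnames(raw) <- list(feat, samp)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = raw),
    colData = S4Vectors::DataFrame(group = factor(grp, levels = groups),
                                   row.names = samp))
  S4Vectors::metadata(se)$scale <- "raw"
  S4Vectors::metadata(se)$seed <- cfg$seed
  truth <- data.frame(feature = feat[de_idx],
                      direction = ifelse(sign_up > 0, "up", "down"),
                      stringsAsFactors = FALSE)
  list(se = se, truth = truth)
}

#' Simulate grouped survival records
#'
#' Exponential event times with group-specific hazards (`hazard` for the
#' first group, `hazard * hazard_ratio` for the second). With probability
#' `censor_rate` a subject is censored at a uniform fraction of its event
#' time.
#'
#' @param cfg a [simConfig()] list.
#' @param groups two stratum labels (default "low", "high").
#' @return survival data.frame (sample, time, event, group).
#' @export
simulateSurvival <- function(cfg, groups = c("low", "high")) {
  set.seed(cfg$seed + 6L)
  n <- cfg$n_surv_per_group
  grp <- rep(groups, each = n)
  rate <- ifelse(grp == groups[2], cfg$hazard * cfg$hazard_ratio, cfg$hazard)
  t_event <- rexp(2L * n, rate = rate)
  cens <- runif(2L * n) < cfg$censor_rate
  time <- ifelse(cens, runif(2L * n) * t_event, t_event)
  data.frame(sample = sprintf("%s%03d", grp, seq_len(2L * n)),
             time = time, event = as.integer(!cens), group = grp,
             stringsAsFactors = FALSE)
}
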