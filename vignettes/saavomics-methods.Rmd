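---
title: "Methods and design of saavomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of saavomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saavomics)
```

# Scope

saavomics implements a desk-scale proteogenomic pipeline for tumor
cohorts: variant-peptide database construction from protein-level
substitutions, SAAV calling from peptide identifications,
cohort-specificity classification, multi-omics (CNV–mRNA–protein)
correlation, label-free differential expression, and survival
stratification. Everything upstream of protein-level inputs — spectral
searching, read alignment, nucleotide variant calling, copy-number
segmentation — is deliberately out of scope: the pipeline starts from a
proteome FASTA, a substitution table, quantification matrices and
SEG-style segments.

# The variant-peptide model

## Digestion

Trypsin cleaves C-terminal of K or R; cleavage is suppressed when the next
residue is proline (`proline_rule = TRUE`, the classic specificity; the
flag reproduces the "Trypsin/P" dialect when off, since search engines
differ and published parameter lists rarely say which was used). Peptides
retain up to `max_missed = 2` internal sites and must be at least
`min_len = 7` residues long — both defaults mirror common search-engine
settings for label-free identification. Protein termini count as cleavage
boundaries, and the initiator methionine is *not* clipped by default
(`clip_met` exposes the alternative). The enumeration is defined
constructively — fully-cleaved fragments are computed once and a
`k`-missed peptide is the join of `k + 1` consecutive fragments — and the
test suite checks it against a brute-force scan of every substring on
random proteins.

## Database construction

For each substitution event the *mutated* sequence is re-digested and
peptides covering the substituted residue are kept. Re-digesting the
mutant, rather than editing the wild-type peptide string, is the correct
generative model: a substitution that creates or destroys a K/R site
changes the tryptic map. When a mutant span has no wild-type peptide of
identical span (over any missed-cleavage count), the record is flagged
`span_changed` and paired with the shortest wild peptide covering the
position.

A mutant peptide only evidences its substitution if it collides with no
wild-type peptide anywhere in the proteome, so candidates matching the
wild universe verbatim are removed. Isoleucine and leucine are isobaric
and indistinguishable by MS; `il_fold = TRUE` performs the collision
filter and all downstream matching after mapping I to L. The default is
OFF — published SAAV tables routinely report I/L-exchanging sites, so
folding silently would hide them — but the flag is honored consistently
across database construction and matching.

Events whose stated reference residue disagrees with the proteome are
collected into a single aggregated error report rather than failing one at
a time: in practice such mismatches mean a stale annotation release, and
the user needs the full list.

One event per variant record: co-occurring nearby substitutions are not
combined into doubly-mutated peptides. Stop gains and indels are out of
scope (a SAAV is a substitution by definition here).

## Site arithmetic and specificity

`substitutionSite()` inverts the construction: given a wild/mutant peptide
pair and the span start, the substitution coordinate is
`start + offset − 1` with `offset` the single differing peptide position;
zero or multiple differences are errors. Cohort specificity is set
algebra over distinct (sample, site) observations: specific to a cohort
iff observed there and nowhere in the other, shared iff in both.
Adjacent-normal (PN) observations are tracked but excluded from the
contrast by default. Per-protein counts follow *occurrence* semantics —
observations across patients, not distinct sites — matching how published
SAAV tables tally "No. of SAAVs"; the packaged fixtures encode those
printed counts and the fixture expansion alternates shared occurrences
across cohorts so every shared site appears in both.

# Quantification statistics

* **RPKM** is the plain formula
  `reads / ((mapped / 1e6) × (length / 1e3))`; zero mapped reads or zero
  length are errors, zero reads give 0.
* **Label-free normalization** log2-transforms and subtracts each sample's
  median over non-missing entries, so all column medians are exactly 0.
  Zeros become missing before the log (log 0 is undefined and a zero LFQ
  intensity means "not quantified"). A scale tag on the container ensures
  log2 is applied exactly once; re-centering is idempotent.
* **Differential expression** uses per-feature Welch tests by default —
  unequal variances between tumor groups are the norm — with Student's
  test available. Significance is the conjunction
  `|log2FC| ≥ log2(2)` AND `p < 0.05` AND `BH q ≤ 0.05`; reported
  workflows mix raw-p and FDR language, so each gate is independently
  configurable (set to `NULL` to drop) and the default enforces all
  three. Features constant in both groups get p = 1 (equal means, with a
  warning) or 0. Summary percentages are rounded half-away-from-zero at 2
  decimals, which is how such tables are printed.
* **BH adjustment** delegates to `stats::p.adjust` after validating
  p ∈ [0, 1]; the tests verify it against a hand-applied step-up.

# Multi-omics integration

Segments are summarized to genes by length-weighted mean of overlapping
segment values (a `max_overlap` alternative picks the dominant segment);
GISTIC-style discrete calls are out of scope since segmentation is not
re-implemented. Per-gene Spearman correlations are computed over shared
samples for each layer pair, with pairwise-complete handling, a minimum of
5 complete pairs per gene, and BH-adjusted two-sided significance at 0.05
(used for the "significant positive mRNA–protein correlation" gate).
Layer means are arithmetic means of per-gene rhos. Concordant sets
require direction consistency by default (up with up, down with down) —
that is what a "positive correlation" intersection means — and chromosome
tallies rank descending with ties broken by label order (1..22, X, Y),
since no sharper ranking rule is available.

# Survival

Kaplan–Meier estimation and the Mantel–Haenszel log-rank test wrap the
survival package (`survfit`/`survdiff`) behind small typed interfaces; the
tests pin them to hand-computed product-limit values and the direct
O−E/hypergeometric-variance formula. Stratification by a feature's
abundance uses a median split — the cutpoint choice (median vs tertile vs
optimal) is genuinely open in such analyses, and the median is the least
tunable option — with ties at the median deterministically assigned to
the low group. Zero events across both groups yield p = 1 with a warning
rather than an error. Cox modeling is intentionally absent: the analyses
this package supports are univariate KM/log-rank.

# The synthetic-data generators

`simConfig()` fixes the emulated study design once: 21 NM and 23 MT
patients with paired PN tissue; 12 NM-specific, 26 shared and 11
MT-specific planted substitution occurrences; peptide detection
probability 0.8 (typical label-free run-to-run overlap; tests that need
exhaustive detection pass `detect_prob = 1` explicitly); a 150-gene ×
30-sample correlation cascade targeting mean Spearman 0.53 (mRNA–protein)
and 0.41 (CNV–protein); 2000-feature label-free matrices with 10% of
features shifted 2-fold and 10% missing cells; exponential survival at
hazard 0.02/month with hazard ratio 3 and 30% censoring.

Proteomes are i.i.d. letters with K+R mass 1/14 (and P at 4.7%), so
fully-cleaved fragments average ≈14 residues under the proline rule —
realistic tryptic peptide lengths without modeling real amino-acid
composition. The cascade draws gene-wise standard-normal copy number,
adds noise to produce mRNA and again to produce protein. The two noise
SDs are calibrated by nested bisection against the *achieved* mean
per-gene Spearman on a fixed-seed calibration draw of 200 genes at the
configured sample count — targeting the finite-sample estimator directly,
which absorbs both the monotone-link choice and the small-sample bias of
per-gene rank correlations. Bisection uses 12 inner and 10 outer
halvings on SD ∈ [0.001, 50] (resolution ≈0.01 SD, far below the
sampling noise of the measured means); a zero correlation target switches
to drawing the downstream layer independently, and targets above 0.99 are
rejected as unreachable. With these sizes the calibration runs in a few
seconds on one core.

What the generators do *not* emulate: real amino-acid composition and
homology (no shared subsequences between proteins, so wild-type collisions
are rarer than in a real proteome), intensity-dependent missingness
(dropout is uniform), correlated genes, arm-level CNV structure, and
non-proportional hazards. Passing tests therefore demonstrate
correctness of the implemented operations under known ground truth, not
performance on real tissue data.

All generators are deterministic given the seed; sub-generators offset
the master seed by fixed constants so stages are independently
reproducible.

# Problem sizes and test budget

The suite runs module tests on small proteomes (≤ 60 proteins, lengths
≤ 500), the digestion-vs-oracle property on 200 random proteins of length
≤ 120, the DE type-I calibration on a 2000-feature 10-vs-10 null, the
log-rank null calibration on 1000 replicates of 30 + 30, and the cascade
recovery at the default 150 × 30 — sizes chosen so the whole suite
completes in well under a minute per heavy property while keeping
Monte-Carlo error comfortably inside the asserted tolerances (binomial
99% intervals for the calibrations, ±0.05 for the cascade means).

# Known limitations

* Exact string matching only: no mass-tolerance or spectrum-level
  rescoring, and no semi-tryptic peptides.
* Variant tables are protein-level; codon-level annotation and splice
  isoforms are not expanded.
* The published tables the fixtures transcribe contain two internal
  inconsistencies (an alternate letter in one NM-specific site and one
  shared site disagreeing with the printed peptide pair, and an
  MT-specific protein count that does not match its table); the fixtures
  reproduce the print verbatim and the consistency checks validate
  positions, which are unambiguous.
* `correlateLayers()` assumes aligned gene identifiers across layers; no
  identifier mapping is attempted.
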