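---
title: "Somatic filtering and two-group recurrence analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic filtering and two-group recurrence analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticsieve)
```

somaticsieve reimplements, at desk scale, the somatic-mutation detection and
filtering procedure used in matched tumor–normal whole-exome studies of
bladder cancer recurrence, together with the gene-level two-group analysis
that compares mutation frequencies between primary and recurrent tumors.
This vignette describes the models, the tunable parameters, and the design
choices made where the procedure left room for interpretation.

## The filtering model

Candidates are enumerated directly from 7-column `samtools mpileup`-style
text (one column of per-read base calls, base qualities and mapping
qualities per position): one candidate per distinct non-reference allele
with at least one supporting tumor read. Each candidate then passes through
a fixed cascade; it exits with exactly one FILTER label, and per-rule
outcomes are retained for attribution.

1. **Heuristic somatic rules.** (i) depth ≥ 10× in tumor *and* matched
   normal; (ii) mean base quality at the site ≥ 15 in both tissues;
   (iii) tumor VAF ≥ 10% with *no* high-quality alt-supporting reads in the
   normal; (iv) ≥ 5 alt-supporting tumor reads. All thresholds are
   inclusive. "High quality" in rule iii is not defined by the source
   procedure; we take base quality ≥ 20 (`hq_bq_threshold`), the common
   somatic-caller convention, and keep it configurable.
2. **Phred-like variant quality.** A binomial evidence score:
   `Q = min(255, −10·log10 P[X ≥ alt_count])` with
   `X ~ Binomial(depth, e)` and `e = 10^(−mean_bq/10)` the error rate
   implied by the mean base quality over all reads at the site. Candidates
   with `Q < 20` are removed. This is a deliberate, documented surrogate
   for consensus-quality scores whose exact definition is tool-internal;
   the binomial tail is computed in log space so small tails do not
   underflow.
3. **Elimination rules.** Mean mapping quality of alt reads < 30 (applied
   to substitutions and indels alike); indels supported by one strand
   only; substitutions within 30 bp (inclusive) of a *predicted indel*.
   We take the predicted-indel list to be the indel candidates that
   survived the heuristic stage, whether or not they later fail an
   elimination rule — they were "predicted" by the preliminary calling
   step that rule iv guards against.
4. **Remappability.** See below.
5. **Germline catalog.** Exact (contig, position, ref, alt) matches
   against a dbSNP-like catalog are labeled `known_germline`; a different
   alt allele at a cataloged site is kept.

The stage order is fixed as listed. The cascade only evaluates later,
more expensive stages for candidates that survived earlier ones, so the
per-stage attrition table is order-dependent; the order itself follows the
narrative order of the original procedure.

VAF uses the raw declared depth (including gap observations) as its
denominator, and the site-level mean base quality is taken over **all**
reads at the position, not only alt-supporting reads — the rule is worded
in terms of the position, and we follow the literal reading. Both
alternatives were considered and rejected as less faithful.

## The remappability filter

Pseudo-genes and segmental duplications produce well-supported candidates
whose reads simply cannot be placed uniquely. For each surviving variant we
build the alternate haplotype, tile every 80 bp window that covers at least
one edited base (for deletions, the junction), and place each read back on
the reference on both strands. A placement is a start offset; its distance
is Hamming for substitution-only reads and, for indel-containing reads, the
minimum Levenshtein distance over reference windows of 80 ± 5 bp starting
at that offset. A read is **uniquely mapped** iff exactly one placement
attains the minimal distance and that distance is ≤ 4; tied minima are
ambiguous, and anything beyond the bound is unmapped. The variant is
discarded iff strictly more than 10% of its reads are not uniquely mapped.

Two implementation routes exist, both verdict-equivalent to an exhaustive
per-offset scan (the exhaustive oracle ships in the test suite):

* **Substitution reads** use seed-and-verify: a placement that can matter
  has distance ≤ 1 (the origin placement mismatches only at the variant
  base), so it must contain one exactly matching read half. All half-length
  windows of the ±80 bp alternate segment are looked up in a precomputed
  reference k-mer table and candidate placements are re-scored by exact
  Hamming distance. Placements at distance ≥ 2 can neither attain nor tie
  the minimum, so the restriction loses nothing.
* **Indel reads** are matched with `Biostrings` approximate matching at an
  edit-distance bound tightened to the indel's own edit cost (the origin
  placement guarantees the minimum is at most that), then re-scored with
  the same per-offset banded Levenshtein definition.

Tiling all windows (rather than sampling a fixed number of reads per
variant) makes the ambiguous fraction exact and reproducible; for the
symmetric exact-duplication case the fraction is unaffected by this choice.
A deletion or insertion inside a homopolymer or short tandem repeat can tie
with shifted placements of itself and be flagged ambiguous; this is a real
ambiguity of placement, not an artifact, and is left as-is.

## Two-group recurrence statistics

A sample counts as mutated for a gene iff it carries ≥ 1 retained variant
inside the gene's target interval, regardless of multiplicity. For each
gene the two-sided Fisher exact test compares mutated-sample counts between
the groups using the minimum-likelihood rule: with margins fixed, sum
`P(X = k)` over all tables no more probable than the observed one, with a
`1e−7` relative tolerance on probability ties. This is the classical
two-sided definition (and the one `stats::fisher.test` implements; the
package computes it directly from `dhyper` and uses `fisher.test` only as
an independent cross-check in the tests). On the study's design —
20 primary vs 17 recurrent samples — the seven printed comparisons
reproduce exactly at two decimals, e.g. 0/20 vs 4/17 → p = 0.04.

No multiple-testing correction is applied: the reported values are raw
per-gene p-values, matching the source presentation. Display rounding is
p to 2 decimals and frequencies to 1 decimal; TSV output keeps full
precision.

The mutation spectrum pools complementary substitutions into six
pyrimidine/purine-paired classes (C>T/G>A, C>A/G>T, C>G/G>C, T>C/A>G,
T>A/A>T, T>G/A>C). Empty input returns zero counts with an `empty`
attribute rather than dividing by zero.

## The synthetic cohort generator

No sequencing data are deposited with the source study, so every stage is
verified against a seeded generator that emulates the study's statistical
structure:

* **Cohort**: 20 primary and 17 recurrent tumors, each with a matched
  normal.
* **Depth**: Poisson with mean 60 per target base.
* **Base qualities**: Normal(30, 5), rounded and clamped to [2, 41].
* **Sequencing error**: substitution to a uniform different base at
  rate 0.001 per read.
* **Germline**: a dbSNP-like catalog covering 0.1% of genome positions;
  each sample is heterozygous at each catalog site with probability 0.3
  (≈ 1 het per 3.3 kb, a realistic exome-scale density). Germline alleles
  appear at fraction 0.5 in both tissues.
* **Somatic**: VAF 0.5 in tumor, 0 in normal (matched peripheral blood;
  normal contamination is configurable but defaults to 0). 15% of somatic
  events are 1–3 bp indels. One somatic variant is planted per mutated
  gene per sample — the comparison counts mutated samples, not mutation
  multiplicity.
* **Group bias**: genes carry either exact mutated-sample counts per group
  (used for the nine-gene comparison panel, whose defaults are the printed
  0/20 vs 4/17, 2/20 vs 0/17, … counts) or an independent per-sample
  mutation probability (background genes, default 0.08).
* **Spectrum**: at C/G reference sites the canonical transition (C>T or
  G>A) is drawn with weight 0.8, making the C>T/G>A class carry roughly
  40% of SNVs — the dominant-class structure reported for bladder tumors.
  The generator accepts any weight; the test suite also verifies that a
  0.5 weight is recovered as the modal class.
* **Duplications**: two exact 500 bp segmental duplications copied between
  background gene bodies. Reads originating inside them drop to mapping
  quality 0 with probability 0.5, modeling multi-mapping without an
  aligner, and variants planted there exercise the remappability filter.

Reads are never materialized as FASTQ: the cascade consumes pileups, and
alignment is out of scope. Deletions mark the anchor column only; the
deleted span's columns are generated independently (single-column
processing — a documented limitation shared with the detector). Identical
configuration and seed give byte-identical outputs; per-sample streams are
derived from the seed and sample identifier, so any sample can be
regenerated in isolation.

For whole-cohort runs the generator can emit a *sparse* pileup form:
per-read rows only for non-reference observations plus exact per-site
depth and mean base quality. Candidate calling consumes either form and
produces identical support statistics (this is asserted in the tests);
the full form is what the text serializer writes.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: alignment and realignment artifacts,
indel representation ambiguity in repeats, strand bias, position-dependent
and correlated error profiles, contamination and subclonal VAF structure,
CNVs, and capture-efficiency variation across targets.

## Problem sizes and numerical choices

The packaged end-to-end recovery run (`study_config()`) uses a 210 kb
reference with 40 × 5 kb gene targets (200 kb of target space) so the full
37-sample cohort runs in minutes on one CPU; module-level defaults use a
100 kb genome with 20 × 2 kb targets. On the recovery run the cascade
achieves somatic SNV sensitivity ≳ 0.95 at precision ≈ 1, removes every
planted catalog germline variant, and reproduces the exclusive-gene
comparison (0/20 vs 4/17, p = 0.04) end to end; these numbers are
recomputed by `scripts/acceptance.R` and asserted in
`tests/testthat/test-acceptance.R`.

One stochastic caveat is inherent to the printed rules: with ~60 normal
reads and error rate 0.001, a normal read occasionally shows the somatic
alt base at base quality ≥ 20, and rule iii then (correctly, per the
rules) removes the true variant. This costs ≈ 2% sensitivity and can,
for some seeds, turn a planted 4/17 gene into a recovered 3/17
(p = 0.09 instead of 0.04). We report whatever the run produces.

Numerical details worth noting: the binomial tail is computed with
`pbinom(…, log.p = TRUE)`; Fisher tie comparison uses the `1e−7` relative
tolerance; variant quality is capped at 255; the remappability fraction is
exact (no read sampling); positions are 1-based inclusive internally (the
R/Bioconductor convention — BED's 0-based half-open frame is converted at
the boundary, which avoids off-by-one drift in a code base whose every
container is 1-based).

## Command-line use

The package functions are the primary interface. A thin wrapper at
`inst/scripts/somaticsieve` exposes `simulate`, `call`, `filter`,
`remap-filter`, `compare`, `qc`, `score` and `run-all` subcommands over
the same functions for shell pipelines; configuration is YAML mirroring
`sim_config()`, flags override config, logs go to stderr and results to
files.

## A worked desk-scale example

```{r example}
design <- tibble::tibble(gene = c("MLL", "EP400"),
                         mut_primary = c(0L, 1L),
                         mut_recurrent = c(2L, 1L))
cfg <- sim_config(seed = 1, genome_length = 20000L, n_genes = 5L,
                  gene_length = 1500L, n_primary = 3L, n_recurrent = 3L,
                  n_duplications = 1L, duplication_length = 200L,
                  gene_design = design)
res <- run_pipeline(cfg)
res$recovery
tidy(res$comparison)
```

```{r plots, fig.width = 6, fig.height = 3}
autoplot(res$comparison)
autoplot(res$spectrum)
```
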