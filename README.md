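# somaticsieve

Tumor–normal somatic variant filtering and two-group recurrence analysis
for matched whole-exome cohorts, at desk scale.

Whole-exome studies of tumor recurrence call somatic mutations by
comparing each tumor to its matched normal (peripheral blood) sample and
then ask which genes are mutated at different frequencies between cohort
groups — for bladder cancer, between primary and recurrent tumors, where
chromatin-modifier genes (*MLL*, *EP400*, *PRDM2*) turn out to be mutated
exclusively in the recurrent group. somaticsieve reimplements that
computational pipeline as a tested R package for anyone who wants to
study, audit, or reuse the procedure without a sequencing center:
candidate detection from pileups, the full filter cascade, a
simulated-read remappability filter, gene-level exact tests, and a seeded
synthetic cohort generator so every stage is verifiable against planted
truth.

## What it implements

* **Candidate detection** from 7-column `samtools mpileup`-style text
  (per-read base calls, base qualities, mapping qualities): one candidate
  per distinct non-reference allele, with support statistics for both
  tissues (`call_candidates()`), plus coverage QC over target intervals
  (`coverage_qc()`).
* **The somatic filter cascade** (`run_filter_cascade()`):
  * heuristic rules — depth ≥ 10× in both tissues, mean base quality ≥ 15
    in both, tumor VAF ≥ 10% with no high-quality alt reads in the normal,
    ≥ 5 supporting reads;
  * a Phred-like variant quality
    `Q = min(255, −10·log₁₀ P[X ≥ alt]), X ~ Bin(depth, 10^(−meanBQ/10))`,
    removing `Q < 20`;
  * elimination rules — alt-read mapping quality < 30, single-strand
    indels, substitutions within 30 bp of a predicted indel;
  * a remappability filter — tile 80 bp reads over the variant haplotype,
    place them back on both strands of the reference, and discard the
    variant when more than 10% of reads have no unique best placement
    (edit distance ≤ 4);
  * a dbSNP-style germline-catalog mask on exact
    (contig, pos, ref, alt) matches.
* **Two-group recurrence statistics** (`compare_groups()`): per-gene
  mutated-sample counts, frequencies, exclusivity calls, and the
  two-sided Fisher exact test (minimum-likelihood rule)

  p = Σ { P(X = k) : P(X = k) ≤ P(X = a) }, X ~ Hypergeom(n₁, n₂, a + b),

  which reproduces the printed comparisons on a 20-vs-17 cohort, e.g.
  0/20 vs 4/17 → p = 0.04. Plus the six-class strand-collapsed mutation
  spectrum (`mutation_spectrum()`).
* **A synthetic two-group cohort generator** (`simulate_cohort()`):
  20 primary + 17 recurrent tumor/normal pairs, Poisson(60) depth,
  Normal(30, 5) base qualities, germline SNPs from a catalog, somatic
  variants at VAF 0.5, exact segmental duplications, group-biased
  per-gene mutation counts, and a truth set for recovery scoring.
* **Closed-form assay scores**: T7E1 indel percentage
  `100·(1 − √(1 − (b+c)/(a+b+c)))`, IHC product score
  (intensity 1–4 × stained fraction), and ellipsoid xenograft volume
  `V = (π/6)·abc`.

Results are tibbles; fitted result objects have `tidy()`/`glance()`
methods and `autoplot()` figures (frequency bars with p-values, spectrum,
cascade attrition). A thin CLI wrapper ships in `inst/scripts/`.

## Worked example

Simulate a small two-group cohort with *MLL* mutated only in the
recurrent group, run the full pipeline, and compare groups:

```r
library(somaticsieve)

design <- tibble::tibble(gene = c("MLL", "EP400"),
                         mut_primary = c(0L, 1L),
                         mut_recurrent = c(2L, 1L))
cfg <- sim_config(seed = 1, genome_length = 20000L, n_genes = 5L,
                  gene_length = 1500L, n_primary = 3L, n_recurrent = 3L,
                  n_duplications = 1L, duplication_length = 200L,
                  gene_design = design)
res <- run_pipeline(cfg)

res$recovery
#> # A tibble: 1 x 11
#>      tp    fn    fp sensitivity precision snv_tp snv_fn snv_fp
#>   <int> <int> <int>       <dbl>     <dbl>  <int>  <int>  <int>
#> 1     4     0     0           1         1      4      0      0
#> # i 3 more variables: snv_sensitivity <dbl>, snv_precision <dbl>,
#> #   germline_survivors <int>

tidy(res$comparison)
#> # A tibble: 5 x 9
#>   gene  mut_g1  n_g1 freq_g1_pct mut_g2  n_g2 freq_g2_pct p_fisher exclusivity
#>   <chr>  <int> <int>       <dbl>  <int> <int>       <dbl>    <dbl> <chr>
#> 1 MLL        0     3         0        2     3        66.7    0.4   group2_only
#> 2 EP400      1     3        33.3      1     3        33.3    1     shared
#> 3 EP300      0     3         0        0     3         0      1     none
#> 4 MLL3       0     3         0        0     3         0      1     none
#> 5 PRDM2      0     3         0        0     3         0      1     none
```

All four planted somatic variants are recovered (sensitivity 1, precision
1), no planted germline variant survives the cascade, and the *MLL* row is
flagged exclusive to the recurrent group. At this toy size (3 vs 3
samples) the Fisher p-value is 0.40; at the emulated study scale
(20 vs 17; `study_config()`) the same exclusive design yields the printed
p = 0.04.

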