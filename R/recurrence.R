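# Gene-level two-group recurrence analysis: mutated-sample counts per gene
# and cohort group, two-sided Fisher exact tests (minimum-likelihood rule),
# exclusivity calls, and the six-class strand-collapsed mutation spectrum.

SPECTRUM_CLASSES <- c("C>T/G>A", "C>A/G>T", "C>G/G>C",
                      "T>C/A>G", "T>A/A>T", "T>G/A>C")

#' Two-sided Fisher exact test on a 2x2 mutation table
#'
#' Tests whether the mutated-sample proportion differs between two groups.
#' With margins fixed, the count in group 1 is hypergeometric; the two-sided
#' p-value sums P(X = k) over every table no more probable than the observed
#' one (minimum-likelihood rule, with a 1e-7 relative tolerance on
#' probability ties). Vectorized over its arguments.
#'
#' @param a Mutated samples in group 1.
#' @param n1 Group 1 size.
#' @param b Mutated samples in group 2.
#' @param n2 Group 2 size.
#' @return Numeric vector of p-values in \[0, 1\].
#' @export
fisher_exact_two_sided <- function(a, n1, b, n2) {
  if (any(a < 0 | b < 0 | n1 < 0 | n2 < 0)) {
    abort("counts must be non-negative.")
  }
  if (any(a > n1 | b > n2)) {
    abort("mutated count exceeds group size.")
  }
  mapply(function(a, n1, b, n2) {
    m <- a + b
    ks <- seq.int(max(0L, m - n2), min(n1, m))
    probs <- dhyper(ks, n1, n2, m)
    p_obs <- dhyper(a, n1, n2, m)
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    min(1, max(0, p))
  }, a, n1, b, n2)
}

#' Build the per-gene two-group mutation table
#'
#' A sample counts as mutated for a gene iff it carries at least one
#' retained (PASS) variant inside the gene's target interval, regardless of
#' mutation multiplicity. Frequencies are percentages of the group size,
#' rounded to one decimal for reporting (`freq_*_pct`); the raw counts are
#' kept alongside.
#'
#' @param variants Tibble of retained variants with `sample_id`, `contig`,
#'   `pos`.
#' @param targets Gene intervals in BED frame (`contig`, `start` 0-based,
#'   `end`, `gene`).
#' @param cohort Cohort design tibble (`sample`, `group`); the first group
#'   level in sort order is group 1.
#' @return Tibble with one row per gene: `gene`, `mut_g1`, `n_g1`,
#'   `freq_g1_pct`, `mut_g2`, `n_g2`, `freq_g2_pct`, with a `groups`
#'   attribute naming the two groups.
#' @export
build_gene_group_table <- function(variants, targets, cohort) {
  groups <- sort(unique(cohort$group))
  if (length(groups) != 2L) {
    abort("cohort must contain exactly two groups.")
  }
  v <- as_tibble(variants)
  missing <- setdiff(unique(v$sample_id), cohort$sample)
  if (length(missing) > 0L) {
    abort(paste0("sample absent from cohort table: ", missing[1]))
  }
  n1 <- sum(cohort$group == groups[1])
  n2 <- sum(cohort$group == groups[2])

  hits <- v %>%
    inner_join(targets, by = "contig", relationship = "many-to-many") %>%
    filter(.data$pos >= .data$start + 1L, .data$pos <= .data$end) %>%
    distinct(.data$gene, .data$sample_id) %>%
    left_join(cohort, by = c(sample_id = "sample")) %>%
    count(.data$gene, .data$group)

  base <- targets %>% distinct(.data$gene)
  g1 <- hits %>% filter(.data$group == groups[1]) %>%
    select("gene", mut_g1 = "n")
  g2 <- hits %>% filter(.data$group == groups[2]) %>%
    select("gene", mut_g2 = "n")
  out <- base %>%
    left_join(g1, by = "gene") %>%
    left_join(g2, by = "gene") %>%
    mutate(
      mut_g1 = if_else(is.na(.data$mut_g1), 0L, .data$mut_g1),
      mut_g2 = if_else(is.na(.data$mut_g2), 0L, .data$mut_g2),
      n_g1 = n1, n_g2 = n2,
      freq_g1_pct = round(100 * .data$mut_g1 / n1, 1),
      freq_g2_pct = round(100 * .data$mut_g2 / n2, 1)
    ) %>%
    select("gene", "mut_g1", "n_g1", "freq_g1_pct",
           "mut_g2", "n_g2", "freq_g2_pct")
  attr(out, "groups") <- groups
  out
}

#' Compare mutation burden between the two cohort groups
#'
#' Adds the two-sided Fisher exact p-value and an exclusivity flag per gene:
#' `group1_only` / `group2_only` when all mutated samples sit in one group,
#' `shared` when both groups are hit, `none` when neither is. Rows are
#' sorted by ascending p-value, then gene name.
#'
#' @param gene_table Output of [build_gene_group_table()], or any tibble
#'   with `gene`, `mut_g1`, `n_g1`, `mut_g2`, `n_g2`.
#' @return A `ss_comparison` tibble with added `p_fisher` and `exclusivity`
#'   columns.
#' @export
compare_groups <- function(gene_table) {
  groups <- attr(gene_table, "groups")
  out <- gene_table %>%
    mutate(
      p_fisher = fisher_exact_two_sided(.data$mut_g1, .data$n_g1,
                                        .data$mut_g2, .data$n_g2),
      exclusivity = case_when(
        .data$mut_g1 == 0L & .data$mut_g2 == 0L ~ "none",
        .data$mut_g1 > 0L & .data$mut_g2 == 0L ~ "group1_only",
        .data$mut_g1 == 0L & .data$mut_g2 > 0L ~ "group2_only",
        TRUE ~ "shared"
      )
    ) %>%
    arrange(.data$p_fisher, .data$gene)
  attr(out, "groups") <- groups
  class(out) <- c("ss_comparison", class(out))
  out
}

#' Six-class strand-collapsed mutation spectrum
#'
#' Pools complementary substitutions into the six pyrimidine/purine-paired
#' classes (C>T/G>A, C>A/G>T, C>G/G>C, T>C/A>G, T>A/A>T, T>G/A>C) and
#' reports counts and fractions. Fractions sum to 1 when at least one SNV is
#' supplied; an empty input yields zero counts, zero fractions and the
#' `empty` attribute set.
#'
#' @param snvs Tibble with single-nucleotide `ref` and `alt` columns.
#' @return Tibble with `class`, `count`, `fraction` (attribute `n_snv`,
#'   logical attribute `empty`).
#' @export
mutation_spectrum <- function(snvs) {
  v <- as_tibble(snvs)
  if (nrow(v) > 0L) {
    if (any(nchar(v$ref) != 1L | nchar(v$alt) != 1L)) {
      abort("mutation_spectrum accepts SNV records only.")
    }
    ref <- toupper(v$ref)
    alt <- toupper(v$alt)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    pur <- ref %in% c("G", "A")
    ref2 <- ifelse(pur, comp[ref], ref)
    alt2 <- ifelse(pur, comp[alt], alt)
    pair <- paste0(ref2, ">", alt2)
    class_of <- c("C>T" = "C>T/G>A", "C>A" = "C>A/G>T", "C>G" = "C>G/G>C",
                  "T>C" = "T>C/A>G", "T>A" = "T>A/A>T", "T>G" = "T>G/A>C")
    if (any(!pair %in% names(class_of))) {
      abort("invalid SNV ref/alt combination.")
    }
    counts <- table(factor(class_of[pair], levels = SPECTRUM_CLASSES))
    out <- tibble(class = SPECTRUM_CLASSES,
                  count = as.integer(counts),
                  fraction = as.integer(counts) / nrow(v))
    attr(out, "n_snv") <- nrow(v)
    attr(out, "empty") <- FALSE
  } else {
    out <- tibble(class = SPECTRUM_CLASSES, count = 0L, fraction = 0)
    attr(out, "n_snv") <- 0L
    attr(out, "empty") <- TRUE
  }
  class(out) <- c("ss_spectrum", class(out))
  out
}

#' Write the group-comparison report as TSV
#'
#' Full-precision p-values are kept in the file; rounding to the display
#' convention (p to 2 decimals, frequencies to 1 decimal) is left to
#' presentation.
#'
#' @param comparison A `ss_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(comparison, path) {
  readr::write_tsv(as_tibble(comparison), path)
  invisible(path)
}
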