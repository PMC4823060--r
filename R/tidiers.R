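# broom-style accessors for cascade and comparison results.

#' Tidy a filter-cascade result
#'
#' One row per candidate with its locus, alleles, key support statistics and
#' final verdict label.
#'
#' @param x A `ss_cascade`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.ss_cascade <- function(x, ...) {
  as_tibble(x) %>%
    select("sample_id", "contig", "pos", "ref", "alt", "type",
           "t_depth", "t_alt", "t_vaf", "vq", "rmf", "filter")
}

#' Summarise a filter-cascade result
#'
#' @param x A `ss_cascade`.
#' @param ... Unused.
#' @return One-row tibble: candidates in, retained, retained fraction, and
#'   the count of distinct failure labels observed.
#' @exportS3Method generics::glance
glance.ss_cascade <- function(x, ...) {
  tb <- as_tibble(x)
  tibble(
    n_candidates = nrow(tb),
    n_pass = sum(tb$filter == "PASS"),
    pass_fraction = if (nrow(tb) > 0) sum(tb$filter == "PASS") / nrow(tb)
                    else NA_real_,
    n_fail_labels = dplyr::n_distinct(tb$filter[tb$filter != "PASS"])
  )
}

#' Tidy a two-group comparison
#'
#' @param x A `ss_comparison`.
#' @param ... Unused.
#' @return The comparison as a plain tibble.
#' @exportS3Method generics::tidy
tidy.ss_comparison <- function(x, ...) {
  as_tibble(x)
}

#' Summarise a two-group comparison
#'
#' @param x A `ss_comparison`.
#' @param alpha Significance bound for counting nominally significant genes.
#' @param ... Unused.
#' @return One-row tibble: genes tested, genes mutated anywhere, exclusive
#'   gene counts per group, and genes with `p_fisher < alpha`.
#' @exportS3Method generics::glance
glance.ss_comparison <- function(x, alpha = 0.05, ...) {
  tb <- as_tibble(x)
  tibble(
    n_genes = nrow(tb),
    n_mutated = sum(tb$mut_g1 + tb$mut_g2 > 0),
    n_group1_only = sum(tb$exclusivity == "group1_only"),
    n_group2_only = sum(tb$exclusivity == "group2_only"),
    n_significant = sum(tb$p_fisher < alpha)
  )
}
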