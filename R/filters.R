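# The somatic filter cascade: heuristic rules (i)-(iv), Phred-like variant
# quality, elimination criteria (i)-(iv), simulated-read remappability, and
# germline-catalog (dbSNP-style) cross-reference. Every candidate exits with
# exactly one final FILTER label; per-rule outcomes are kept as columns for
# full attribution.

FILTER_LABELS <- c("PASS", "fail_coverage", "fail_baseq", "fail_vaf",
                   "fail_normal_evidence", "fail_support", "fail_varqual",
                   "fail_mapq", "fail_strand", "fail_indel_proximity",
                   "fail_remap", "known_germline")

#' Filter cascade configuration
#'
#' All thresholds are inclusive exactly as printed in the rules they encode:
#' coverage >= 10x in both tissues, mean base quality >= 15 in both, tumor
#' VAF >= 10%, no high-quality alt-supporting normal reads (base quality
#' >= 20 defines "high quality"), >= 5 supporting tumor reads, Phred-like
#' variant quality >= 20, mean alt-read mapping quality >= 30, indels on both
#' strands, substitutions farther than 30 bp from any preliminary indel.
#'
#' @param min_depth Minimum depth in tumor and normal (reads).
#' @param min_mean_bq Minimum mean base quality at the site, both tissues.
#' @param min_vaf Minimum tumor variant allele fraction.
#' @param max_hq_alt_normal Maximum high-quality alt reads allowed in normal.
#' @param hq_bq_threshold Base quality defining a high-quality normal alt read.
#' @param min_alt_reads Minimum tumor alt-supporting reads.
#' @param min_variant_quality Minimum Phred-like variant quality.
#' @param min_mapping_quality Minimum mean mapping quality over tumor alt reads.
#' @param indel_strand_rule Require indel support on both strands.
#' @param indel_proximity_window Window (bases, inclusive) around preliminary
#'   indels within which substitutions are eliminated.
#' @param dbsnp_version_label Version label of the germline catalog.
#' @return A `ss_filter_config` list.
#' @export
filter_config <- function(min_depth = 10L,
                          min_mean_bq = 15,
                          min_vaf = 0.10,
                          max_hq_alt_normal = 0L,
                          hq_bq_threshold = 20,
                          min_alt_reads = 5L,
                          min_variant_quality = 20,
                          min_mapping_quality = 30,
                          indel_strand_rule = TRUE,
                          indel_proximity_window = 30L,
                          dbsnp_version_label = "137") {
  vals <- c(min_depth, min_mean_bq, min_vaf, max_hq_alt_normal,
            hq_bq_threshold, min_alt_reads, min_variant_quality,
            min_mapping_quality, indel_proximity_window)
  if (any(vals < 0)) abort("all thresholds must be >= 0.")
  if (min_vaf < 0 || min_vaf > 1) abort("min_vaf must lie in [0, 1].")
  structure(list(
    min_depth = min_depth, min_mean_bq = min_mean_bq, min_vaf = min_vaf,
    max_hq_alt_normal = max_hq_alt_normal,
    hq_bq_threshold = hq_bq_threshold, min_alt_reads = min_alt_reads,
    min_variant_quality = min_variant_quality,
    min_mapping_quality = min_mapping_quality,
    indel_strand_rule = indel_strand_rule,
    indel_proximity_window = indel_proximity_window,
    dbsnp_version_label = dbsnp_version_label
  ), class = "ss_filter_config")
}

#' Apply the heuristic somatic rules (i)-(iv)
#'
#' Evaluates, without short-circuiting, (i) sufficient coverage in both
#' tissues, (ii) mean base quality at the site in both tissues, (iii) tumor
#' VAF with no high-quality alt evidence in the normal, and (iv) minimum
#' tumor alt read support. Matched normal statistics are mandatory.
#'
#' @param candidates Candidate tibble from [call_candidates()].
#' @param config A [filter_config()].
#' @return `candidates` with logical columns `rule_coverage`, `rule_baseq`,
#'   `rule_vaf`, `rule_normal_evidence`, `rule_support`.
#' @export
apply_heuristic_rules <- function(candidates, config = filter_config()) {
  needed <- c("n_depth", "n_mean_bq", "n_hq_alt")
  if (!all(needed %in% names(candidates)) ||
      anyNA(candidates[needed])) {
    abort("matched normal statistics are mandatory for the heuristic rules.")
  }
  candidates %>% mutate(
    rule_coverage = .data$t_depth >= config$min_depth &
      .data$n_depth >= config$min_depth,
    rule_baseq = .data$t_mean_bq >= config$min_mean_bq &
      .data$n_mean_bq >= config$min_mean_bq,
    rule_vaf = .data$t_vaf >= config$min_vaf,
    rule_normal_evidence = .data$n_hq_alt <= config$max_hq_alt_normal,
    rule_support = .data$t_alt >= config$min_alt_reads
  )
}

#' Phred-like variant quality from a binomial error model
#'
#' Scores the evidence that the alt reads exceed sequencing noise:
#' `Q = min(255, -10 log10 P[X >= alt_count])` with
#' `X ~ Binomial(depth, e)` and `e = 10^(-mean_base_quality / 10)` the
#' site-level error probability implied by the mean base quality over all
#' reads. Zero alt reads score 0.
#'
#' @param alt_count,depth,mean_bq Vectors of tumor alt counts, depths and
#'   mean base qualities.
#' @return Numeric vector of Phred-like qualities, capped at 255.
#' @export
variant_quality <- function(alt_count, depth, mean_bq) {
  stopifnot(all(depth >= 1L))
  e <- 10^(-mean_bq / 10)
  logp <- pbinom(alt_count - 1, depth, e, lower.tail = FALSE, log.p = TRUE)
  q <- pmin(255, -10 * logp / log(10))
  ifelse(alt_count == 0, 0, q)
}

#' Compute variant quality for a candidate table
#'
#' @param candidates Candidate tibble with `t_alt`, `t_depth`, `t_mean_bq`.
#' @return `candidates` with a `vq` column (see [variant_quality()]).
#' @export
compute_variant_quality <- function(candidates) {
  candidates %>%
    mutate(vq = variant_quality(.data$t_alt, .data$t_depth, .data$t_mean_bq))
}

#' Apply the elimination criteria (i)-(iv)
#'
#' (i) variant quality below the Phred-like bound, (ii) mean mapping quality
#' of tumor alt-supporting reads below 30 (applied to substitutions and
#' indels alike), (iii) indels supported by a single DNA strand, and (iv)
#' substitutions within the proximity window (inclusive) of a preliminary
#' indel of the same sample on the same contig.
#'
#' @param candidates Candidate tibble with a `vq` column (see
#'   [compute_variant_quality()]).
#' @param config A [filter_config()].
#' @param preliminary_indels Tibble of predicted indels (`sample_id`,
#'   `contig`, `pos`). Defaults to the indel rows of `candidates`.
#' @return `candidates` with logical columns `rule_varqual`, `rule_mapq`,
#'   `rule_strand`, `rule_indel_proximity`.
#' @export
apply_elimination_rules <- function(candidates, config = filter_config(),
                                    preliminary_indels = NULL) {
  if (!"vq" %in% names(candidates)) {
    abort("run compute_variant_quality() before the elimination rules.")
  }
  if (is.null(preliminary_indels)) {
    preliminary_indels <- candidates %>%
      filter(.data$type %in% c("INS", "DEL")) %>%
      select("sample_id", "contig", "pos")
  }
  out <- candidates %>% mutate(
    rule_varqual = .data$vq >= config$min_variant_quality,
    rule_mapq = .data$t_alt_mean_mq >= config$min_mapping_quality,
    rule_strand = !(config$indel_strand_rule &
                      .data$type %in% c("INS", "DEL") &
                      (.data$t_alt_fwd == 0L | .data$t_alt_rev == 0L))
  )
  w <- config$indel_proximity_window
  near <- rep(FALSE, nrow(out))
  if (nrow(preliminary_indels) > 0L && nrow(out) > 0L) {
    snv_idx <- which(out$type == "SNV")
    for (i in snv_idx) {
      sel <- preliminary_indels$sample_id == out$sample_id[i] &
        preliminary_indels$contig == out$contig[i]
      if (any(abs(preliminary_indels$pos[sel] - out$pos[i]) <= w)) {
        near[i] <- TRUE
      }
    }
  }
  out %>% mutate(rule_indel_proximity = !near)
}

#' Mask candidates present in a germline catalog
#'
#' A candidate is labeled as known germline iff the (contig, position, ref,
#' alt) quadruple matches a catalog record exactly; a different alt allele
#' at the same site is kept.
#'
#' @param candidates Candidate tibble.
#' @param known_germline Catalog tibble with `contig`, `pos`, `ref`, `alt`
#'   (e.g. from [read_vcf()]).
#' @return `candidates` with a logical `rule_not_germline` column (`FALSE`
#'   when the candidate is in the catalog).
#' @export
dbsnp_mask <- function(candidates, known_germline) {
  key <- paste(known_germline$contig, known_germline$pos,
               known_germline$ref, known_germline$alt)
  candidates %>%
    mutate(rule_not_germline = !paste(.data$contig, .data$pos, .data$ref,
                                      .data$alt) %in% key)
}

first_fail_label <- function(flags) {
  # flags: named list of logical vectors (TRUE = pass), in cascade order
  n <- length(flags[[1]])
  label <- rep("PASS", n)
  for (nm in rev(names(flags))) {
    f <- flags[[nm]]
    label[!is.na(f) & !f] <- nm
  }
  label
}

#' Run the full filter cascade
#'
#' Stages run in fixed order: heuristic rules, variant quality, elimination
#' rules, remappability, germline catalog. Later stages are evaluated only
#' for candidates surviving earlier ones (attrition is therefore
#' order-dependent); per-rule outcomes within a stage are all recorded. The
#' remappability stage requires `reference` and the catalog stage
#' `known_germline`; a `NULL` for either skips that stage with a message.
#'
#' @param candidates Candidate tibble from [call_candidates()] (one or more
#'   samples; rule iv is applied within sample).
#' @param config A [filter_config()].
#' @param reference Named character vector of contig sequences, or `NULL` to
#'   skip the remappability stage.
#' @param known_germline Germline catalog tibble, or `NULL` to skip.
#' @param remap_cfg A [remap_config()].
#' @param remap_idx Optional precomputed [remap_index()] for `reference`.
#' @return A `ss_cascade` tibble: the candidates plus rule columns, `vq`,
#'   `rmf` and the final `filter` label, with an `attrition` attribute
#'   (tibble of stage, entering, failed).
#' @export
run_filter_cascade <- function(candidates, config = filter_config(),
                               reference = NULL, known_germline = NULL,
                               remap_cfg = remap_config(), remap_idx = NULL) {
  cand <- as_tibble(candidates)
  if (nrow(cand) == 0L) {
    out <- cand %>% mutate(filter = character(0))
    attr(out, "attrition") <- tibble(stage = character(0),
                                     entering = integer(0),
                                     failed = integer(0))
    class(out) <- c("ss_cascade", class(out))
    return(out)
  }
  cand <- apply_heuristic_rules(cand, config)
  cand <- compute_variant_quality(cand)
  prelim_indels <- cand %>%
    filter(.data$type %in% c("INS", "DEL"),
           .data$rule_coverage, .data$rule_baseq, .data$rule_vaf,
           .data$rule_normal_evidence, .data$rule_support) %>%
    select("sample_id", "contig", "pos")
  cand <- apply_elimination_rules(cand, config, prelim_indels)

  flags <- list(
    fail_coverage = cand$rule_coverage,
    fail_baseq = cand$rule_baseq,
    fail_vaf = cand$rule_vaf,
    fail_normal_evidence = cand$rule_normal_evidence,
    fail_support = cand$rule_support,
    fail_varqual = cand$rule_varqual,
    fail_mapq = cand$rule_mapq,
    fail_strand = cand$rule_strand,
    fail_indel_proximity = cand$rule_indel_proximity
  )
  pre_label <- first_fail_label(flags)
  surviving <- pre_label == "PASS"

  # remappability stage (survivors only)
  cand$rmf <- NA_real_
  remap_pass <- rep(NA, nrow(cand))
  if (is.null(reference)) {
    inform("no reference supplied: remappability stage skipped.")
  } else if (any(surviving)) {
    rm_res <- remap_filter(cand[surviving, , drop = FALSE], reference,
                           remap_cfg, index = remap_idx)
    cand$rmf[surviving] <- rm_res$rmf
    remap_pass[surviving] <- rm_res$remap_keep
  }
  cand$rule_remap <- remap_pass
  flags$fail_remap <- remap_pass

  # germline catalog stage (survivors of all earlier stages)
  if (is.null(known_germline)) {
    inform("no germline catalog supplied: known_germline stage skipped.")
    cand$rule_not_germline <- NA
  } else {
    cand <- dbsnp_mask(cand, known_germline)
  }
  flags$known_germline <- cand$rule_not_germline

  label <- first_fail_label(flags)
  cand$filter <- factor(label, levels = FILTER_LABELS)

  # stage-sequential attrition
  stages <- names(flags)
  entering <- integer(length(stages))
  failed <- integer(length(stages))
  alive <- rep(TRUE, nrow(cand))
  for (k in seq_along(stages)) {
    f <- flags[[k]]
    entering[k] <- sum(alive)
    fail_k <- alive & !is.na(f) & !f
    failed[k] <- sum(fail_k)
    alive <- alive & !fail_k
  }
  attrition <- tibble(stage = stages, entering = entering, failed = failed)
  attr(cand, "attrition") <- attrition
  attr(cand, "filter_config") <- config
  class(cand) <- c("ss_cascade", class(cand))
  cand
}

#' Attrition table of a filter cascade result
#'
#' @param cascade A `ss_cascade` from [run_filter_cascade()].
#' @return Tibble with columns `stage`, `entering`, `failed`.
#' @export
cascade_attrition <- function(cascade) {
  a <- attr(cascade, "attrition")
  if (is.null(a)) abort("not a cascade result.")
  a
}

#' Extract PASS variants from a cascade result
#'
#' @param cascade A `ss_cascade`.
#' @return Tibble of candidates whose final label is `PASS`.
#' @export
pass_variants <- function(cascade) {
  out <- as_tibble(cascade) %>% filter(.data$filter == "PASS")
  attr(out, "attrition") <- NULL
  attr(out, "filter_config") <- NULL
  class(out) <- setdiff(class(out), "ss_cascade")
  out
}
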