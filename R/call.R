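# Candidate enumeration from paired tumor/normal pileups, and coverage QC.
#
# One candidate is emitted per distinct non-reference allele (SNV alt base,
# insertion sequence, deletion length) with at least one supporting tumor
# read. Support statistics are computed for both tissues; downstream filters
# act on these numbers only.

#' Enumerate candidate somatic variants from paired pileups
#'
#' Scans position-matched tumor and normal pileups and emits one candidate
#' per distinct non-reference allele observed in the tumor. Indels are
#' reported as left-anchored VCF-style records (shared anchor base). Support
#' statistics per candidate and tissue: depth, alt read count, alt counts by
#' strand, VAF (alt/depth over all reads including gaps), mean base quality
#' over all reads at the site, mean mapping quality over alt-supporting
#' reads, and the count of high-quality alt reads in the normal (base
#' quality >= `hq_bq_threshold`).
#'
#' @param tumor,normal `ss_pileup` objects, sorted by (contig, position).
#' @param reference Named character vector of contig sequences.
#' @param sample_id Sample identifier attached to the candidates.
#' @param hq_bq_threshold Base-quality bound defining a "high quality"
#'   alt-supporting normal read (default 20).
#' @return Tibble of candidates with columns `sample_id`, `contig`, `pos`,
#'   `ref`, `alt`, `type`, tumor stats (`t_depth`, `t_alt`, `t_alt_fwd`,
#'   `t_alt_rev`, `t_vaf`, `t_mean_bq`, `t_alt_mean_mq`) and normal stats
#'   (`n_depth`, `n_alt`, `n_hq_alt`, `n_mean_bq`).
#' @export
call_candidates <- function(tumor, normal, reference, sample_id = "sample",
                            hq_bq_threshold = 20) {
  t_sites <- pileup_sites(tumor)
  n_sites <- pileup_sites(normal)
  check_sorted(t_sites, "tumor")
  check_sorted(n_sites, "normal")
  check_reference_agreement(t_sites, reference)
  check_reference_agreement(n_sites, reference)

  t_reads <- as_tibble(tumor)
  alt_reads <- t_reads %>%
    filter(.data$call %in% c("snv", "ins", "del"),
           is.na(.data$allele) | .data$allele != "N")
  if (nrow(alt_reads) == 0L) {
    return(empty_candidates())
  }
  cand <- alt_reads %>%
    group_by(.data$contig, .data$pos, .data$ref, .data$call, .data$allele) %>%
    summarise(
      t_alt = n(),
      t_alt_fwd = sum(.data$strand == "+"),
      t_alt_rev = sum(.data$strand == "-"),
      t_alt_mean_mq = mean(.data$mapq),
      .groups = "drop"
    )

  # site-level mean base quality: taken from the site table when the
  # generator pre-aggregated it (sparse pileups), otherwise from the reads
  # at candidate sites (cheap positional prefilter first; the semi_join
  # settles contig ties exactly)
  cand_sites <- cand %>% distinct(.data$contig, .data$pos)
  if ("mean_bq" %in% names(t_sites)) {
    t_site_stats <- t_sites %>%
      select("contig", "pos", t_mean_bq = "mean_bq")
  } else {
    t_site_stats <- t_reads[t_reads$pos %in% cand_sites$pos, ] %>%
      semi_join(cand_sites, by = c("contig", "pos")) %>%
      group_by(.data$contig, .data$pos) %>%
      summarise(t_mean_bq = mean(.data$baseq), .groups = "drop")
  }
  n_all <- as_tibble(normal)
  n_reads <- n_all[n_all$pos %in% cand_sites$pos, ] %>%
    semi_join(cand_sites, by = c("contig", "pos"))
  if ("mean_bq" %in% names(n_sites)) {
    n_site_stats <- n_sites %>%
      select("contig", "pos", n_mean_bq = "mean_bq")
  } else {
    n_site_stats <- n_reads %>%
      group_by(.data$contig, .data$pos) %>%
      summarise(n_mean_bq = mean(.data$baseq), .groups = "drop")
  }
  n_alt_stats <- n_reads %>%
    filter(.data$call %in% c("snv", "ins", "del")) %>%
    group_by(.data$contig, .data$pos, .data$call, .data$allele) %>%
    summarise(
      n_alt = n(),
      n_hq_alt = sum(.data$baseq >= hq_bq_threshold),
      .groups = "drop"
    )

  cand <- cand %>%
    left_join(t_sites %>% select("contig", "pos", t_depth = "depth"),
              by = c("contig", "pos")) %>%
    left_join(t_site_stats, by = c("contig", "pos")) %>%
    left_join(n_sites %>% select("contig", "pos", n_depth = "depth"),
              by = c("contig", "pos")) %>%
    left_join(n_site_stats, by = c("contig", "pos")) %>%
    left_join(n_alt_stats, by = c("contig", "pos", "call", "allele")) %>%
    mutate(
      n_depth = if_else(is.na(.data$n_depth), 0L, .data$n_depth),
      n_mean_bq = if_else(is.na(.data$n_mean_bq), 0, .data$n_mean_bq),
      n_alt = if_else(is.na(.data$n_alt), 0L, .data$n_alt),
      n_hq_alt = if_else(is.na(.data$n_hq_alt), 0L, .data$n_hq_alt),
      t_vaf = .data$t_alt / .data$t_depth
    )

  # VCF-style left-anchored alleles
  vcf <- vcf_alleles(cand$contig, cand$pos, cand$ref, cand$call, cand$allele,
                     reference)
  cand %>%
    mutate(sample_id = sample_id, alt = vcf$alt, ref = vcf$ref,
           type = vcf$type) %>%
    select("sample_id", "contig", "pos", "ref", "alt", "type",
           "t_depth", "t_alt", "t_alt_fwd", "t_alt_rev", "t_vaf",
           "t_mean_bq", "t_alt_mean_mq",
           "n_depth", "n_alt", "n_hq_alt", "n_mean_bq") %>%
    arrange(.data$contig, .data$pos, .data$alt)
}

empty_candidates <- function() {
  tibble(sample_id = character(0), contig = character(0), pos = integer(0),
         ref = character(0), alt = character(0), type = character(0),
         t_depth = integer(0), t_alt = integer(0), t_alt_fwd = integer(0),
         t_alt_rev = integer(0), t_vaf = numeric(0), t_mean_bq = numeric(0),
         t_alt_mean_mq = numeric(0), n_depth = integer(0),
         n_alt = integer(0), n_hq_alt = integer(0), n_mean_bq = numeric(0))
}

check_sorted <- function(sites, label) {
  ok <- sites %>%
    group_by(.data$contig) %>%
    summarise(sorted = !is.unsorted(.data$pos, strictly = FALSE),
              .groups = "drop")
  if (!all(ok$sorted)) {
    abort(paste0(label, " pileup is not sorted by (contig, position)."))
  }
}

check_reference_agreement <- function(sites, reference) {
  for (ctg in unique(sites$contig)) {
    sel <- sites$contig == ctg
    expect <- ref_seq(reference, ctg, sites$pos[sel], sites$pos[sel])
    bad <- which(expect != sites$ref[sel])
    if (length(bad) > 0L) {
      abort(paste0("reference base disagreement at ", ctg, ":",
                   sites$pos[sel][bad[1]], " (pileup ",
                   sites$ref[sel][bad[1]], ", reference ",
                   expect[bad[1]], ")."))
    }
  }
}

# convert pileup-encoded alleles to left-anchored VCF ref/alt/type
vcf_alleles <- function(contig, pos, anchor, call, allele, reference) {
  n <- length(pos)
  ref_out <- anchor
  alt_out <- character(n)
  type <- character(n)
  snv <- call == "snv"
  alt_out[snv] <- allele[snv]
  type[snv] <- "SNV"
  ins <- call == "ins"
  if (any(ins)) {
    alt_out[ins] <- paste0(anchor[ins], substring(allele[ins], 2L))
    type[ins] <- "INS"
  }
  del <- call == "del"
  if (any(del)) {
    lens <- as.integer(substring(allele[del], 2L))
    idx <- which(del)
    for (k in seq_along(idx)) {
      i <- idx[k]
      ref_out[i] <- ref_seq(reference, contig[i], pos[i], pos[i] + lens[k])
    }
    alt_out[del] <- anchor[del]
    type[del] <- "DEL"
  }
  list(ref = ref_out, alt = alt_out, type = type)
}

#' Coverage QC over target intervals
#'
#' Mean depth over all target bases (bases absent from the pileup count as
#' depth 0) and the fraction of target bases covered at >= `min_depth`
#' (inclusive threshold, default 10).
#'
#' @param pileup A `ss_pileup` object or a site-level tibble with `contig`,
#'   `pos`, `depth`.
#' @param targets Target intervals in BED frame (`contig`, `start` 0-based,
#'   `end`, `gene`).
#' @param min_depth Inclusive coverage threshold.
#' @return Tibble with `n_target_bases`, `mean_depth`, `frac_covered`.
#' @export
coverage_qc <- function(pileup, targets, min_depth = 10L) {
  if (nrow(targets) == 0L) abort("targets must be non-empty.")
  sites <- if (inherits(pileup, "ss_pileup")) pileup_sites(pileup)
           else as_tibble(pileup)
  tpos <- targets %>%
    mutate(pos1 = purrr::map2(.data$start + 1L, .data$end, seq.int)) %>%
    select("contig", "pos1") %>%
    tidyr::unnest("pos1") %>%
    rename(pos = "pos1") %>%
    distinct()
  joined <- tpos %>%
    left_join(sites %>% select("contig", "pos", "depth"),
              by = c("contig", "pos")) %>%
    mutate(depth = if_else(is.na(.data$depth), 0L, .data$depth))
  tibble(
    n_target_bases = nrow(joined),
    mean_depth = mean(joined$depth),
    frac_covered = mean(joined$depth >= min_depth)
  )
}
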