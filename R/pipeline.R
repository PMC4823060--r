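# End-to-end driver: simulate -> call -> filter -> remap -> compare, with
# truth-based recovery scoring, coverage QC aggregation and optional file
# output with a provenance block.

#' Run the full pipeline on a simulated cohort
#'
#' For every sample: simulate tumor/normal pileups, enumerate candidates,
#' and run the filter cascade (heuristics, variant quality, eliminations,
#' remappability, germline catalog). Retained variants feed the gene-level
#' two-group comparison and the mutation spectrum; truth-based recovery
#' metrics (sensitivity, precision) are computed for somatic SNVs and
#' overall. All randomness flows from the config seed.
#'
#' @param config A [sim_config()], or a ready-made `ss_cohort` from
#'   [simulate_cohort()].
#' @param filter_cfg A [filter_config()].
#' @param remap_cfg A [remap_config()].
#' @param out_dir Optional directory; when given, the retained-variant VCF,
#'   comparison TSV, attrition TSV and a provenance YAML are written there.
#' @param quiet Suppress per-sample progress messages.
#' @return A `ss_pipeline_result` list: `cascade` (all candidates with
#'   verdicts), `pass` (retained variants), `comparison`, `spectrum`,
#'   `coverage` (per-sample QC), `recovery`, `truth`, `cohort`, `targets`,
#'   `config`.
#' @export
run_pipeline <- function(config = sim_config(), filter_cfg = filter_config(),
                         remap_cfg = remap_config(), out_dir = NULL,
                         quiet = TRUE) {
  cohort_obj <- if (inherits(config, "ss_cohort")) config
                else simulate_cohort(config)
  cfg <- cohort_obj$config
  reference <- cohort_obj$reference
  targets <- cohort_obj$targets

  remap_idx <- remap_index(reference$genome, remap_cfg)
  cascades <- list()
  coverage <- list()
  for (s in cohort_obj$cohort$sample) {
    if (!quiet) inform(paste0("processing sample ", s))
    tr <- cohort_obj$truth[cohort_obj$truth$sample == s, , drop = FALSE]
    pu <- simulate_sample_pileups(reference, tr, cfg, s, sparse = TRUE)
    cands <- call_candidates(pu$tumor, pu$normal, reference$genome,
                             sample_id = s,
                             hq_bq_threshold = filter_cfg$hq_bq_threshold)
    casc <- withCallingHandlers(
      run_filter_cascade(cands, filter_cfg, reference = reference$genome,
                         known_germline = cohort_obj$catalog,
                         remap_cfg = remap_cfg, remap_idx = remap_idx),
      message = function(m) invokeRestart("muffleMessage")
    )
    coverage[[s]] <- coverage_qc(pu$tumor, targets) %>%
      mutate(sample = s, .before = 1)
    cascades[[s]] <- casc
  }
  attritions <- purrr::map(cascades, cascade_attrition)
  attrition <- bind_rows(attritions) %>%
    group_by(.data$stage) %>%
    summarise(entering = sum(.data$entering), failed = sum(.data$failed)) %>%
    slice(match(attritions[[1]]$stage, .data$stage))
  all_cands <- bind_rows(purrr::map(cascades, as_tibble))
  attr(all_cands, "attrition") <- attrition
  class(all_cands) <- c("ss_cascade", class(all_cands))

  pass <- pass_variants(all_cands)
  gene_table <- build_gene_group_table(pass, targets, cohort_obj$cohort)
  comparison <- compare_groups(gene_table)
  spectrum <- mutation_spectrum(pass %>% filter(.data$type == "SNV"))
  coverage <- bind_rows(coverage)
  recovery <- evaluate_recovery(pass, cohort_obj$truth, cohort_obj$catalog)

  result <- structure(list(
    cascade = all_cands, pass = pass, comparison = comparison,
    spectrum = spectrum, coverage = coverage, recovery = recovery,
    truth = cohort_obj$truth, cohort = cohort_obj$cohort,
    targets = targets, config = cfg
  ), class = "ss_pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf(pass %>% mutate(filter = "PASS", vaf = .data$t_vaf,
                              mq = .data$t_alt_mean_mq),
              file.path(out_dir, "somatic.vcf"))
    write_comparison_tsv(comparison, file.path(out_dir, "comparison.tsv"))
    readr::write_tsv(attrition, file.path(out_dir, "attrition.tsv"))
    readr::write_tsv(coverage, file.path(out_dir, "coverage_qc.tsv"))
    write_provenance(cfg, file.path(out_dir, "provenance.yaml"))
  }
  result
}

write_provenance <- function(config, path) {
  lines <- c(
    paste0("package: somaticsieve ",
           as.character(utils::packageVersion("somaticsieve"))),
    paste0("generated: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    "config:",
    paste0("  ", names(unclass(config))[!vapply(unclass(config), is.null, logical(1))], ": ",
           vapply(unclass(config)[!vapply(unclass(config), is.null, logical(1))],
                  function(x) paste(format(x), collapse = " "), character(1)))
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Score recovered variants against the simulation truth set
#'
#' Matches retained calls to planted variants on the exact
#' (sample, contig, position, ref, alt) record. Reports sensitivity and
#' precision overall and for somatic SNVs, and the number of planted
#' catalog (dbSNP-like) germline variants that survived filtering.
#'
#' @param pass Tibble of retained variants (`sample_id`, `contig`, `pos`,
#'   `ref`, `alt`, `type`).
#' @param truth Truth tibble from [simulate_cohort()] (`sample`, `contig`,
#'   `pos`, `ref`, `alt`, `type`, `origin`).
#' @param catalog Germline catalog tibble.
#' @return One-row tibble: `tp`, `fn`, `fp`, `sensitivity`, `precision`,
#'   `snv_tp`, `snv_fn`, `snv_fp`, `snv_sensitivity`, `snv_precision`,
#'   `germline_survivors`.
#' @export
evaluate_recovery <- function(pass, truth, catalog) {
  key <- function(s, ctg, pos, ref, alt) paste(s, ctg, pos, ref, alt)
  som <- truth %>% filter(.data$origin == "somatic")
  truth_key <- key(som$sample, som$contig, som$pos, som$ref, som$alt)
  call_key <- key(pass$sample_id, pass$contig, pass$pos, pass$ref, pass$alt)
  tp <- sum(truth_key %in% call_key)
  fn <- sum(!truth_key %in% call_key)
  fp <- sum(!call_key %in% truth_key)

  som_snv <- som %>% filter(.data$type == "SNV")
  snv_truth_key <- key(som_snv$sample, som_snv$contig, som_snv$pos,
                       som_snv$ref, som_snv$alt)
  pass_snv <- pass %>% filter(.data$type == "SNV")
  snv_call_key <- key(pass_snv$sample_id, pass_snv$contig, pass_snv$pos,
                      pass_snv$ref, pass_snv$alt)
  snv_tp <- sum(snv_truth_key %in% snv_call_key)
  snv_fn <- sum(!snv_truth_key %in% snv_call_key)
  snv_fp <- sum(!snv_call_key %in% snv_truth_key)

  germ <- truth %>% filter(.data$origin == "germline") %>%
    semi_join(catalog, by = c("contig", "pos", "ref", "alt"))
  germ_key <- key(germ$sample, germ$contig, germ$pos, germ$ref, germ$alt)
  tibble(
    tp = tp, fn = fn, fp = fp,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    snv_tp = snv_tp, snv_fn = snv_fn, snv_fp = snv_fp,
    snv_sensitivity = if (snv_tp + snv_fn > 0) snv_tp / (snv_tp + snv_fn)
                      else NA_real_,
    snv_precision = if (snv_tp + snv_fp > 0) snv_tp / (snv_tp + snv_fp)
                    else NA_real_,
    germline_survivors = sum(call_key %in% germ_key)
  )
}
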