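# Heuristic somatic rules, variant quality, elimination criteria, germline
# catalog masking, and cascade behavior

test_that("heuristic rules i-iv are applied with inclusive thresholds", {
  cfg <- filter_config()

  shallow <- apply_heuristic_rules(
    make_candidate(t_depth = 9L, t_alt = 5L, t_vaf = 5 / 9, n_depth = 15L),
    cfg)
  expect_false(shallow$rule_coverage)

  # vaf below 10% fails rule iii even though alt >= 5 satisfies rule iv
  low_vaf <- apply_heuristic_rules(
    make_candidate(t_depth = 60L, t_alt = 5L, t_vaf = 5 / 60), cfg)
  expect_false(low_vaf$rule_vaf)
  expect_true(low_vaf$rule_support)

  # one high-quality alt read in the normal is disqualifying
  tainted <- apply_heuristic_rules(
    make_candidate(t_depth = 50L, t_alt = 6L, t_vaf = 0.12, n_alt = 1L,
                   n_hq_alt = 1L), cfg)
  expect_false(tainted$rule_normal_evidence)

  # boundary candidate passes every rule at exactly the threshold
  boundary <- apply_heuristic_rules(
    make_candidate(t_depth = 10L, n_depth = 10L, t_alt = 5L, t_vaf = 0.10,
                   t_mean_bq = 15, n_mean_bq = 15, t_alt_fwd = 3L,
                   t_alt_rev = 2L), cfg)
  expect_true(all(unlist(boundary[grep("^rule_", names(boundary))])))

  expect_error(apply_heuristic_rules(make_candidate(n_depth = NA_integer_)),
               "normal")
})

test_that("variant quality follows the binomial tail model", {
  expect_equal(variant_quality(0, 30, 30), 0)
  expect_equal(variant_quality(30, 30, 30), 255)  # tail ~1e-90, capped

  # frozen against a direct summation of the binomial tail, written
  # independently of the pbinom-based implementation
  oracle_vq <- function(alt, depth, mean_bq) {
    e <- 10^(-mean_bq / 10)
    p_tail <- sum(vapply(alt:depth, function(k) {
      choose(depth, k) * e^k * (1 - e)^(depth - k)
    }, numeric(1)))
    min(255, -10 * log10(p_tail))
  }
  expect_equal(variant_quality(5, 20, 30), oracle_vq(5, 20, 30),
               tolerance = 1e-8)
  expect_equal(variant_quality(5, 50, 15), oracle_vq(5, 50, 15),
               tolerance = 1e-8)
  expect_equal(variant_quality(5, 50, 15), 16.86116, tolerance = 1e-4)
})

test_that("elimination rules ii-iv act on strand, mapping quality and
           indel proximity", {
  cfg <- filter_config()
  one_strand <- compute_variant_quality(
    make_candidate(type = "INS", ref = "A", alt = "AAG", t_alt = 7L,
                   t_alt_fwd = 7L, t_alt_rev = 0L))
  out <- apply_elimination_rules(one_strand, cfg)
  expect_false(out$rule_strand)

  low_mq <- compute_variant_quality(make_candidate(t_alt_mean_mq = 29.5))
  expect_false(apply_elimination_rules(low_mq, cfg)$rule_mapq)

  # window boundary: |delta| = 30 eliminated, 31 kept
  indels <- tibble::tibble(sample_id = "S1", contig = "chr1", pos = 1025L)
  near <- compute_variant_quality(make_candidate(pos = 995L))
  far <- compute_variant_quality(make_candidate(pos = 1056L))
  expect_false(apply_elimination_rules(near, cfg, indels)$rule_indel_proximity)
  expect_true(apply_elimination_rules(far, cfg, indels)$rule_indel_proximity)
  # a different sample's indel does not count
  other <- indels; other$sample_id <- "S2"
  expect_true(apply_elimination_rules(near, cfg, other)$rule_indel_proximity)
})

test_that("germline catalog masking matches the exact quadruple", {
  catalog <- tibble::tibble(contig = "chr1", pos = 1000L, ref = "A",
                            alt = "T")
  hit <- dbsnp_mask(make_candidate(), catalog)
  expect_false(hit$rule_not_germline)
  other_alt <- dbsnp_mask(make_candidate(alt = "G"), catalog)
  expect_true(other_alt$rule_not_germline)
  empty <- dbsnp_mask(make_candidate(), catalog[0, ])
  expect_true(empty$rule_not_germline)
})

test_that("cascade assigns exactly one final label and attrition sums add up", {
  cands <- dplyr::bind_rows(
    make_candidate(pos = 100L),
    make_candidate(pos = 300L, t_depth = 9L),
    make_candidate(pos = 500L, t_alt = 4L, t_vaf = 4 / 60,
                   t_alt_fwd = 2L, t_alt_rev = 2L),
    make_candidate(pos = 700L, n_hq_alt = 1L, n_alt = 1L)
  )
  suppressMessages(casc <- run_filter_cascade(cands, filter_config()))
  expect_equal(as.character(casc$filter),
               c("PASS", "fail_coverage", "fail_vaf",
                 "fail_normal_evidence"))
  a <- cascade_attrition(casc)
  expect_equal(sum(a$failed) + sum(casc$filter == "PASS"), nrow(cands))
  expect_equal(a$entering[1], nrow(cands))
  # entering counts are sequential: each stage sees the survivors
  expect_equal(a$entering[-1], (a$entering - a$failed)[-nrow(a)])
})

test_that("relaxing every threshold passes all but cataloged candidates", {
  genome <- random_genome(3000, seed = 21)
  noop <- filter_config(min_depth = 0, min_mean_bq = 0, min_vaf = 0,
                        max_hq_alt_normal = 1e9, min_alt_reads = 0,
                        min_variant_quality = 0, min_mapping_quality = 0,
                        indel_strand_rule = FALSE,
                        indel_proximity_window = 0L)
  catalog <- tibble::tibble(contig = "chr1", pos = 1000L, ref = "A",
                            alt = "T")
  cands <- dplyr::bind_rows(
    make_candidate(pos = 100L, t_depth = 3L, t_alt = 1L, t_vaf = 1 / 3,
                   t_alt_fwd = 1L, t_alt_rev = 0L, t_mean_bq = 5,
                   n_depth = 0L, n_mean_bq = 0, t_alt_mean_mq = 0),
    make_candidate(pos = 1000L,
                   ref = substr(genome[["chr1"]], 1000, 1000))
  )
  cands$ref[1] <- substr(genome[["chr1"]], 100, 100)
  cands$alt[1] <- setdiff(c("A", "C", "G", "T"), cands$ref[1])[1]
  catalog$ref <- cands$ref[2]
  catalog$alt <- cands$alt[2] <- setdiff(c("A", "C", "G", "T"),
                                         cands$ref[2])[1]
  suppressMessages(
    casc <- run_filter_cascade(cands, noop, reference = genome,
                               known_germline = catalog))
  expect_equal(as.character(casc$filter), c("PASS", "known_germline"))
})

test_that("relaxing a single threshold never converts PASS to fail", {
  cfg <- filter_config()
  withr::with_seed(17, {
    cands <- purrr::map_dfr(1:40, function(i) {
      depth <- sample(5:80, 1)
      alt <- sample(0:depth, 1)
      fwd <- sample(0:alt, 1)
      make_candidate(
        pos = sample.int(10000L, 1), t_depth = depth, t_alt = alt,
        t_vaf = alt / depth, t_alt_fwd = fwd, t_alt_rev = alt - fwd,
        t_mean_bq = runif(1, 5, 40), t_alt_mean_mq = runif(1, 0, 60),
        n_depth = sample(0:80, 1), n_hq_alt = sample(0:2, 1),
        n_mean_bq = runif(1, 5, 40),
        type = sample(c("SNV", "INS", "DEL"), 1))
    })
    cands$alt[cands$type == "INS"] <- paste0(cands$ref[cands$type == "INS"], "AG")
    cands$ref[cands$type == "DEL"] <- paste0(cands$ref[cands$type == "DEL"], "AT")
    suppressMessages(strict <- run_filter_cascade(cands, cfg))
    relaxations <- list(
      filter_config(min_depth = 5L), filter_config(min_mean_bq = 10),
      filter_config(min_vaf = 0.05), filter_config(max_hq_alt_normal = 2L),
      filter_config(min_alt_reads = 2L),
      filter_config(min_variant_quality = 10),
      filter_config(min_mapping_quality = 10),
      filter_config(indel_strand_rule = FALSE),
      filter_config(indel_proximity_window = 5L)
    )
    for (rc in relaxations) {
      suppressMessages(relaxed <- run_filter_cascade(cands, rc))
      was_pass <- strict$filter == "PASS"
      expect_true(all(relaxed$filter[was_pass] == "PASS"))
    }
  })
})
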