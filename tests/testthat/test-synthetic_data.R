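# Synthetic cohort generator: determinism, planted-signal consistency,
# configuration invariants

test_that("reference simulation is deterministic with exact duplications", {
  cfg <- small_sim_config()
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$duplications, r2$duplications)
  d <- r1$duplications
  expect_equal(nrow(d), 1L)
  src <- substr(r1$genome[["chr1"]], d$src_start, d$src_end)
  cp <- substr(r1$genome[["chr1"]], d$copy_start, d$copy_end)
  expect_identical(src, cp)
})

test_that("impossible configurations are rejected", {
  expect_error(sim_config(genome_length = 100L, n_duplications = 2L,
                          duplication_length = 500L),
               "duplication span")
  expect_error(sim_config(tumor_vaf = 1.5), "probabilities")
  expect_error(sim_config(n_primary = 0L), "group sizes")
  expect_error(sim_config(n_genes = 60L, gene_length = 2000L,
                          genome_length = 100000L),
               "do not fit")
})

test_that("planted VAF and error structure appear in the pileups", {
  # VAF 1, error 0: every tumor read at the somatic site is alt; the normal
  # stream carries zero alt observations
  cfg <- small_sim_config(tumor_vaf = 1, base_error_rate = 0)
  co <- simulate_cohort(cfg)
  som <- co$truth[co$truth$origin == "somatic" &
                    co$truth$type == "SNV", ][1, ]
  pu <- simulate_sample_pileups(co$reference,
                                co$truth[co$truth$sample == som$sample, ],
                                cfg, som$sample)
  treads <- tibble::as_tibble(pu$tumor)
  at_site <- treads[treads$pos == som$pos, ]
  expect_true(all(at_site$call == "snv"))
  expect_true(all(at_site$allele == som$alt))
  nreads <- tibble::as_tibble(pu$normal)
  expect_equal(sum(nreads$pos == som$pos & nreads$call != "ref"), 0L)
})

test_that("empirical depth matches the Poisson model", {
  cfg <- small_sim_config()   # 7,500 target sites
  co <- simulate_cohort(cfg)
  pu <- simulate_sample_pileups(co$reference,
                                co$truth[co$truth$sample == "P01", ],
                                cfg, "P01")
  d <- pileup_sites(pu$tumor)$depth
  expect_gt(length(d), 2000L)
  expect_lt(abs(mean(d) - 60) / 60, 0.10)
})

test_that("tumor alt counts track depth x VAF within binomial noise", {
  cfg <- sim_config(seed = 3, genome_length = 50000L, n_genes = 10L,
                    gene_length = 3000L, n_primary = 2L, n_recurrent = 2L,
                    n_duplications = 0L,
                    gene_design = tibble::tibble(
                      gene = sprintf("G%02d", 1:10)[c(1, 2)],
                      p_primary = c(1, 1), p_recurrent = c(1, 1)),
                    somatic_rate = 1, somatic_indel_fraction = 0,
                    germline_site_rate = 0)
  co <- simulate_cohort(cfg)
  total_alt <- 0; total_exp <- 0; total_var <- 0
  for (s in co$cohort$sample) {
    tr <- co$truth[co$truth$sample == s, ]
    pu <- simulate_sample_pileups(co$reference, tr, cfg, s)
    reads <- tibble::as_tibble(pu$tumor)
    sites <- pileup_sites(pu$tumor)
    for (p in tr$pos[tr$origin == "somatic"]) {
      dep <- sites$depth[sites$pos == p]
      total_alt <- total_alt + sum(reads$pos == p & reads$call == "snv")
      total_exp <- total_exp + dep * cfg$tumor_vaf
      total_var <- total_var + dep * cfg$tumor_vaf * (1 - cfg$tumor_vaf)
    }
  }
  expect_lt(abs(total_alt - total_exp), 3 * sqrt(total_var))
})

test_that("explicit gene-group assignment reproduces the designed table", {
  design <- tibble::tibble(gene = "MLL", p_primary = 0, p_recurrent = 1)
  cfg <- sim_config(seed = 5, genome_length = 20000L, n_genes = 3L,
                    gene_length = 2000L, n_primary = 4L, n_recurrent = 5L,
                    n_duplications = 0L, somatic_rate = 0,
                    gene_design = design)
  co <- simulate_cohort(cfg)
  row <- co$gene_group_truth[co$gene_group_truth$gene == "MLL", ]
  expect_equal(row$primary, 0L)
  expect_equal(row$recurrent, 5L)

  # exact-count assignment
  design2 <- tibble::tibble(gene = "MLL", mut_primary = 0L,
                            mut_recurrent = 3L)
  cfg2 <- sim_config(seed = 5, genome_length = 20000L, n_genes = 3L,
                     gene_length = 2000L, n_primary = 4L, n_recurrent = 5L,
                     n_duplications = 0L, somatic_rate = 0,
                     gene_design = design2)
  co2 <- simulate_cohort(cfg2)
  row2 <- co2$gene_group_truth[co2$gene_group_truth$gene == "MLL", ]
  expect_equal(row2$primary, 0L)
  expect_equal(row2$recurrent, 3L)
})

test_that("somatic truth variants lie inside their gene's interval", {
  cfg <- small_sim_config()
  co <- simulate_cohort(cfg)
  som <- co$truth[co$truth$origin == "somatic", ]
  tg <- co$targets
  for (i in seq_len(nrow(som))) {
    g <- tg[tg$gene == som$gene[i], ]
    expect_true(som$pos[i] >= g$start + 1L && som$pos[i] <= g$end)
  }
  # germline variants are shared between tumor and normal truth by design:
  # each germline row applies to both tissues of the sample
  expect_true(all(co$truth$origin %in% c("germline", "somatic")))
})

test_that("cohort file output is byte-identical across runs", {
  cfg <- sim_config(seed = 9, genome_length = 6000L, n_genes = 2L,
                    gene_length = 1500L, n_primary = 1L, n_recurrent = 1L,
                    n_duplications = 1L, duplication_length = 100L,
                    gene_design = tibble::tibble(gene = "MLL",
                                                 mut_primary = 1L,
                                                 mut_recurrent = 1L))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) >= 8L)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("sparse and full pileups yield identical candidate statistics", {
  cfg <- small_sim_config()
  co <- simulate_cohort(cfg)
  tr <- co$truth[co$truth$sample == "R01", ]
  sp <- simulate_sample_pileups(co$reference, tr, cfg, "R01", sparse = TRUE)
  fu <- simulate_sample_pileups(co$reference, tr, cfg, "R01", sparse = FALSE)
  c_sp <- call_candidates(sp$tumor, sp$normal, co$reference$genome, "R01")
  c_fu <- call_candidates(fu$tumor, fu$normal, co$reference$genome, "R01")
  expect_equal(c_sp, c_fu)
  expect_error(write_pileup(sp$tumor, withr::local_tempfile()), "sparse")
})
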