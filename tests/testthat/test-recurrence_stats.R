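# Two-group Fisher tests, gene-group tables, exclusivity, spectrum

test_that("two-sided Fisher test agrees with enumeration and fisher.test", {
  # brute-force minimum-likelihood enumeration, independent of the
  # implementation's dhyper path
  oracle <- function(a, n1, b, n2) {
    m <- a + b
    ks <- max(0, m - n2):min(n1, m)
    pr <- vapply(ks, function(k) {
      choose(n1, k) * choose(n2, m - k) / choose(n1 + n2, m)
    }, numeric(1))
    p_obs <- pr[ks == a]
    min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  }
  withr::with_seed(13, {
    for (rep in 1:60) {
      n1 <- sample(1:25, 1); n2 <- sample(1:25, 1)
      a <- sample(0:n1, 1); b <- sample(0:n2, 1)
      p <- fisher_exact_two_sided(a, n1, b, n2)
      expect_equal(p, oracle(a, n1, b, n2), tolerance = 1e-10)
      ft <- stats::fisher.test(matrix(c(a, n1 - a, b, n2 - b), 2, 2))
      expect_equal(p, ft$p.value, tolerance = 1e-7)
    }
  })
})

test_that("Fisher test is symmetric, bounded, and handles degenerate tables", {
  expect_equal(fisher_exact_two_sided(0, 20, 0, 17), 1)
  withr::with_seed(14, {
    for (rep in 1:20) {
      n1 <- sample(1:20, 1); n2 <- sample(1:20, 1)
      a <- sample(0:n1, 1); b <- sample(0:n2, 1)
      p1 <- fisher_exact_two_sided(a, n1, b, n2)
      p2 <- fisher_exact_two_sided(b, n2, a, n1)
      expect_equal(p1, p2, tolerance = 1e-12)
      expect_true(p1 >= 0 && p1 <= 1)
    }
  })
  # equal proportions at identical n give p = 1
  expect_equal(fisher_exact_two_sided(4, 10, 4, 10), 1)
  expect_error(fisher_exact_two_sided(-1, 10, 0, 10), "non-negative")
  expect_error(fisher_exact_two_sided(11, 10, 0, 10), "exceeds")
})

test_that("the seven printed two-group p-values are reproduced exactly", {
  tables <- list(
    list(0, 20, 4, 17, 0.04),  # MLL / EP400 / PRDM2
    list(2, 20, 0, 17, 0.49),  # MLL3
    list(3, 20, 0, 17, 0.23),  # EP300
    list(2, 20, 3, 17, 0.64),  # FGFR3
    list(6, 20, 1, 17, 0.10),  # HRAS
    list(3, 20, 4, 17, 0.68),  # TP53
    list(1, 20, 2, 17, 0.58)   # RB1
  )
  for (tb in tables) {
    expect_equal(round(fisher_exact_two_sided(tb[[1]], tb[[2]], tb[[3]],
                                              tb[[4]]), 2),
                 tb[[5]])
  }
})

test_that("gene-group tables count samples once and report percentages", {
  targets <- tibble::tibble(contig = "chr1",
                            start = c(0L, 1000L),
                            end = c(500L, 1500L),
                            gene = c("MLL", "TP53"))
  cohort <- tibble::tibble(
    sample = c(sprintf("P%02d", 1:20), sprintf("R%02d", 1:17)),
    group = c(rep("primary", 20), rep("recurrent", 17)))
  # 4 recurrent samples with MLL variants; one with three variants in the
  # same gene counts once; 6 primary with TP53
  variants <- dplyr::bind_rows(
    tibble::tibble(sample_id = c("R01", "R02", "R03", "R04"),
                   contig = "chr1", pos = c(10L, 20L, 30L, 40L)),
    tibble::tibble(sample_id = "R01", contig = "chr1", pos = c(50L, 60L)),
    tibble::tibble(sample_id = sprintf("P%02d", 1:6), contig = "chr1",
                   pos = 1200L)
  )
  tab <- build_gene_group_table(variants, targets, cohort)
  mll <- tab[tab$gene == "MLL", ]
  expect_equal(mll$mut_g2, 4L)
  expect_equal(mll$freq_g2_pct, 23.5)
  expect_equal(mll$mut_g1, 0L)
  tp53 <- tab[tab$gene == "TP53", ]
  expect_equal(tp53$mut_g1, 6L)
  expect_equal(tp53$freq_g1_pct, 30.0)

  expect_error(
    build_gene_group_table(
      tibble::tibble(sample_id = "X99", contig = "chr1", pos = 10L),
      targets, cohort),
    "absent")
})

test_that("group comparison flags exclusivity and sorts by p-value", {
  tab <- tibble::tibble(
    gene = c("MLL", "TP53", "EMPTY", "MLL3"),
    mut_g1 = c(0L, 3L, 0L, 2L), n_g1 = 20L,
    freq_g1_pct = c(0, 15, 0, 10),
    mut_g2 = c(4L, 4L, 0L, 0L), n_g2 = 17L,
    freq_g2_pct = c(23.5, 23.5, 0, 0))
  attr(tab, "groups") <- c("primary", "recurrent")
  cmp <- compare_groups(tab)
  expect_equal(cmp$gene[1], "MLL")
  expect_equal(round(cmp$p_fisher[cmp$gene == "MLL"], 2), 0.04)
  expect_equal(cmp$exclusivity[cmp$gene == "MLL"], "group2_only")
  expect_equal(cmp$exclusivity[cmp$gene == "MLL3"], "group1_only")
  expect_equal(cmp$exclusivity[cmp$gene == "TP53"], "shared")
  expect_equal(cmp$exclusivity[cmp$gene == "EMPTY"], "none")
  expect_equal(cmp$p_fisher[cmp$gene == "EMPTY"], 1)
  expect_false(is.unsorted(cmp$p_fisher))

  g <- glance(cmp)
  expect_equal(g$n_genes, 4L)
  expect_equal(g$n_group2_only, 1L)
  expect_s3_class(tidy(cmp), "tbl_df")
})

test_that("mutation spectrum pools complementary substitutions", {
  snvs <- tibble::tibble(ref = c("A", "T", "C"), alt = c("G", "C", "T"))
  sp <- mutation_spectrum(snvs)
  expect_equal(sp$count[sp$class == "T>C/A>G"], 2L)
  expect_equal(sp$count[sp$class == "C>T/G>A"], 1L)
  expect_equal(sum(sp$fraction), 1)

  empty <- mutation_spectrum(snvs[0, ])
  expect_true(attr(empty, "empty"))
  expect_equal(sum(empty$count), 0L)
  expect_equal(sum(empty$fraction), 0)

  expect_error(mutation_spectrum(tibble::tibble(ref = "AT", alt = "A")),
               "SNV")
})

test_that("spectrum recovers a planted dominant class from the simulator", {
  cfg <- small_sim_config(ct_bias = 0.5, somatic_rate = 0.6,
                          somatic_indel_fraction = 0)
  res <- run_pipeline(cfg)
  sp <- res$spectrum
  expect_gt(attr(sp, "n_snv"), 0L)
  expect_equal(sum(sp$fraction), 1)
  expect_equal(sp$class[which.max(sp$count)], "C>T/G>A")
})
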