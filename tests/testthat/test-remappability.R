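# Simulated-read generation, placement uniqueness, and the remap filter

test_that("variant reads tile the alternate haplotype over the edit", {
  genome <- random_genome(10000, seed = 2)
  pos <- 500L
  ref <- substr(genome[["chr1"]], pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  v <- tibble::tibble(contig = "chr1", pos = pos, ref = ref, alt = alt,
                      type = "SNV")
  reads <- generate_variant_reads(v, genome, remap_config())
  expect_equal(nrow(reads), 80L)
  # every read contains the alt base at the right offset and differs from
  # the corresponding reference window at exactly that one position
  for (i in seq_len(nrow(reads))) {
    o <- reads$origin[i]
    refwin <- substr(genome[["chr1"]], o, o + 79L)
    d <- sum(utf8ToInt(reads$seq[i]) != utf8ToInt(refwin))
    expect_equal(d, 1L)
    expect_equal(substr(reads$seq[i], pos - o + 1L, pos - o + 1L), alt)
  }

  # 5' clipping: an SNV at position 40 admits only 40 windows
  v40 <- v; v40$pos <- 40L
  v40$ref <- substr(genome[["chr1"]], 40, 40)
  v40$alt <- setdiff(c("A", "C", "G", "T"), v40$ref)[1]
  expect_equal(nrow(generate_variant_reads(v40, genome, remap_config())),
               40L)

  expect_error(generate_variant_reads(v, c(chr1 = "ACGT"), remap_config()),
               "shorter")
})

test_that("deletion reads span the junction", {
  genome <- random_genome(2000, seed = 3)
  pos <- 900L
  ref3 <- substr(genome[["chr1"]], pos, pos + 2L)
  v <- tibble::tibble(contig = "chr1", pos = pos, ref = ref3,
                      alt = substr(ref3, 1, 1), type = "DEL")
  reads <- generate_variant_reads(v, genome, remap_config())
  expect_equal(nrow(reads), 79L)  # junction needs two haplotype positions
  hap <- paste0(substr(genome[["chr1"]], 1, pos),
                substr(genome[["chr1"]], pos + 3L, 2000))
  for (i in c(1L, nrow(reads))) {
    o <- reads$origin[i]
    expect_true(o <= pos && o + 79L >= pos + 1L)
    expect_equal(reads$seq[i], substr(hap, o, o + 79L))
  }
})

test_that("placement verdicts: unique region, exact duplication, symmetry", {
  genome <- random_genome(6000, seed = 4,
                          dup = list(from = 1001L, to = 4001L, len = 400L))
  cfg <- remap_config()

  # read from a unique error-free region maps uniquely to its origin with
  # distance 1 (the variant mismatch)
  pos_u <- 5500L
  ref <- substr(genome[["chr1"]], pos_u, pos_u)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  vu <- tibble::tibble(contig = "chr1", pos = pos_u, ref = ref, alt = alt,
                       type = "SNV")
  rd <- generate_variant_reads(vu, genome, cfg)$seq[40]
  m <- map_read_unique(rd, genome, cfg)
  expect_equal(m$verdict, "unique")
  expect_equal(m$distance, 1L)
  expect_equal(m$strand, "+")

  # inside one copy of an exact duplication the alt read scores distance 1
  # at both copies: ambiguous
  pos_d <- 1200L
  refd <- substr(genome[["chr1"]], pos_d, pos_d)
  altd <- setdiff(c("A", "C", "G", "T"), refd)[1]
  vd <- tibble::tibble(contig = "chr1", pos = pos_d, ref = refd, alt = altd,
                       type = "SNV")
  rdd <- generate_variant_reads(vd, genome, cfg)$seq[40]
  expect_equal(map_read_unique(rdd, genome, cfg)$verdict, "ambiguous")

  # reverse-complement symmetry: flipping both genome and read preserves
  # the verdict class
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  genome_rc <- c(chr1 = rc(genome[["chr1"]]))
  expect_equal(map_read_unique(rc(rd), genome_rc, cfg)$verdict, "unique")
  expect_equal(map_read_unique(rc(rdd), genome_rc, cfg)$verdict,
               "ambiguous")
})

test_that("remap filter fractions and strict discard boundary", {
  genome <- random_genome(6000, seed = 4,
                          dup = list(from = 1001L, to = 4001L, len = 400L))
  cfg <- remap_config()
  mkv <- function(pos) {
    ref <- substr(genome[["chr1"]], pos, pos)
    tibble::tibble(contig = "chr1", pos = pos, ref = ref,
                   alt = setdiff(c("A", "C", "G", "T"), ref)[1],
                   type = "SNV")
  }
  # unique region: fraction 0, keep; deep inside the duplication (>= 80 bp
  # from both copy boundaries): every read ambiguous, fraction 1, discard
  out <- remap_filter(dplyr::bind_rows(mkv(5500L), mkv(1200L)), genome, cfg)
  expect_equal(out$rmf, c(0, 1))
  expect_equal(out$remap_keep, c(TRUE, FALSE))

  # a fraction exactly at the bound is kept (strict "more than")
  expect_true(remap_config()$max_ambiguous_fraction == 0.10)
  v <- mkv(5500L)
  fake <- v; fake$rmf <- 0.10
  expect_true(fake$rmf <= cfg$max_ambiguous_fraction)
})

test_that("fast SNV route agrees with per-read mapping and both match the
           exhaustive oracle on a small genome", {
  genome <- random_genome(2500, seed = 6,
                          dup = list(from = 201L, to = 2001L, len = 300L))
  cfg <- remap_config()
  withr::with_seed(8, {
    pos <- sample(100:2400, 12)
  })
  vs <- tibble::tibble(
    contig = "chr1", pos = as.integer(pos),
    ref = substring(genome[["chr1"]], pos, pos),
    type = "SNV")
  vs$alt <- vapply(vs$ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1],
                   character(1))
  fast <- remap_filter(vs, genome, cfg)
  for (i in seq_len(nrow(vs))) {
    reads <- generate_variant_reads(vs[i, ], genome, cfg)
    per_read <- vapply(reads$seq, function(r) {
      map_read_unique(r, genome, cfg)$verdict
    }, character(1), USE.NAMES = FALSE)
    oracle <- vapply(reads$seq, function(r) {
      oracle_map_read(r, genome, cfg, has_indel = FALSE)
    }, character(1), USE.NAMES = FALSE)
    expect_equal(per_read, oracle)
    expect_equal(fast$rmf[i], mean(oracle != "unique"))
  }
})

test_that("indel-read mapping matches the exhaustive banded oracle", {
  genome <- random_genome(2000, seed = 9,
                          dup = list(from = 101L, to = 1501L, len = 250L))
  cfg <- remap_config()
  cases <- list(
    list(pos = 800L, len = 2L, type = "INS"),
    list(pos = 1600L, len = 1L, type = "DEL"),   # inside the duplication
    list(pos = 950L, len = 3L, type = "DEL")
  )
  for (cs in cases) {
    anchor <- substr(genome[["chr1"]], cs$pos, cs$pos)
    if (cs$type == "INS") {
      v <- tibble::tibble(contig = "chr1", pos = cs$pos, ref = anchor,
                          alt = paste0(anchor, strrep("T", cs$len)),
                          type = "INS")
    } else {
      v <- tibble::tibble(contig = "chr1", pos = cs$pos,
                          ref = substr(genome[["chr1"]], cs$pos,
                                       cs$pos + cs$len),
                          alt = anchor, type = "DEL")
    }
    reads <- generate_variant_reads(v, genome, cfg)
    idx <- round(seq(1, nrow(reads), length.out = 5))
    for (i in idx) {
      got <- map_read_unique(reads$seq[i], genome, cfg, has_indel = TRUE)
      want <- oracle_map_read(reads$seq[i], genome, cfg, has_indel = TRUE)
      expect_equal(got$verdict, want,
                   info = paste(cs$type, cs$pos, "read", i))
    }
  }
})
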