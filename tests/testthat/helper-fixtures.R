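# shared builders for desk-scale fixtures (everything generated in code)

toy_path <- function(file) {
  system.file("extdata", "toy", file, package = "somaticsieve")
}

# uniform random genome, optionally with one exact duplication
random_genome <- function(len, seed = 1, dup = NULL) {
  withr::with_seed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    if (!is.null(dup)) {
      substr(s, dup$to, dup$to + dup$len - 1L) <-
        substr(s, dup$from, dup$from + dup$len - 1L)
    }
    c(chr1 = s)
  })
}

# one-row candidate with sensible clean defaults, overridable per test
make_candidate <- function(...) {
  defaults <- tibble::tibble(
    sample_id = "S1", contig = "chr1", pos = 1000L, ref = "A", alt = "T",
    type = "SNV", t_depth = 60L, t_alt = 30L, t_alt_fwd = 15L,
    t_alt_rev = 15L, t_vaf = 0.5, t_mean_bq = 30, t_alt_mean_mq = 60,
    n_depth = 60L, n_alt = 0L, n_hq_alt = 0L, n_mean_bq = 30
  )
  overrides <- list(...)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

# small simulation config for fast cohort tests
small_sim_config <- function(seed = 1, ...) {
  design <- tibble::tibble(gene = c("MLL", "EP400"),
                           mut_primary = c(0L, 1L),
                           mut_recurrent = c(2L, 1L))
  sim_config(seed = seed, genome_length = 20000L, n_genes = 5L,
             gene_length = 1500L, n_primary = 3L, n_recurrent = 3L,
             n_duplications = 1L, duplication_length = 200L,
             gene_design = design, ...)
}

# exhaustive per-offset mapping oracle: scans every offset of both strands,
# scoring by Hamming distance (substitution reads) or the minimum
# Levenshtein distance over windows of read_length +/- band (indel reads);
# fully independent of the seeded implementation path
oracle_map_read <- function(read, genome, config = remap_config(),
                            has_indel = FALSE) {
  L <- nchar(read)
  k <- config$max_edit_distance
  bw <- config$band_width
  best <- Inf
  ties <- 0L
  for (ctg in names(genome)) {
    s <- genome[[ctg]]
    n <- nchar(s)
    for (pat in c(read, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(read))))) {
      if (!has_indel) {
        rchars <- utf8ToInt(pat)
        starts <- seq_len(n - L + 1L)
        wins <- substring(s, starts, starts + L - 1L)
        d <- vapply(wins, function(w) sum(utf8ToInt(w) != rchars),
                    integer(1), USE.NAMES = FALSE)
      } else {
        starts <- seq_len(n - 1L)
        d <- vapply(starts, function(o) {
          lo <- max(1L, L - bw)
          hi <- min(L + bw, n - o + 1L)
          if (hi < lo) return(Inf)
          lens <- seq.int(lo, hi)
          wins <- substring(s, o, o + lens - 1L)
          min(utils::adist(pat, wins))
        }, numeric(1))
      }
      m <- min(d)
      if (m < best) {
        best <- m
        ties <- sum(d == m)
      } else if (m == best) {
        ties <- ties + sum(d == m)
      }
    }
  }
  if (best > k) "unmapped" else if (ties == 1L) "unique" else "ambiguous"
}
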