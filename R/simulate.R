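# Seeded synthetic tumor/normal cohort generator.
#
# Emulates the statistical structure of a two-group whole-exome study:
# ~60x Poisson depth over exome-like gene targets, Normal(30, 5) Phred base
# qualities clamped to [2, 41], germline heterozygous SNPs drawn from a
# dbSNP-like catalog, somatic SNVs/indels at a configurable VAF, exact
# segmental duplications that degrade mapping quality, and per-gene
# group-biased mutation assignment with a recorded truth set.

#' Simulation configuration
#'
#' All randomness of the generator flows from `seed`; identical configs give
#' byte-identical outputs. The defaults encode the emulated study design:
#' 20 primary and 17 recurrent tumor samples, each with a matched normal,
#' mean depth 60, somatic VAF 0.5 in tumor and 0 in normal, and a mutation
#' spectrum in which the C>T/G>A class dominates (canonical-transition weight
#' 0.8 at C/G reference sites, giving that class roughly 40% of SNVs against
#' 12-17% for each other class).
#'
#' @param seed Integer seed.
#' @param genome_length Reference length in bases (single contig).
#' @param n_duplications Number of exact segmental duplications.
#' @param duplication_length Length of each duplicated segment (bases).
#' @param n_genes Number of gene target intervals.
#' @param gene_length Length of each gene interval (bases).
#' @param n_primary,n_recurrent Group sizes (samples).
#' @param mean_depth Mean sequencing depth (Poisson per site).
#' @param base_error_rate Per-read substitution error probability.
#' @param base_quality_mean,base_quality_sd Normal model for Phred base
#'   qualities, clamped to `base_quality_range`.
#' @param base_quality_range Inclusive clamp bounds for base qualities.
#' @param mapping_quality Mapping quality outside duplications.
#' @param duplication_mq0_prob Probability that a read originating inside a
#'   duplicated segment is assigned mapping quality 0 (multi-mapping proxy).
#' @param germline_site_rate Fraction of genome positions that are catalog
#'   (dbSNP-like) polymorphic sites.
#' @param germline_het_prob Per-sample probability of a heterozygous genotype
#'   at each catalog site.
#' @param somatic_rate Background per-gene per-sample somatic mutation
#'   probability, used for genes without an explicit design row.
#' @param somatic_indel_fraction Fraction of somatic events that are indels
#'   (split evenly between insertions and deletions, lengths 1-3).
#' @param tumor_vaf,normal_vaf Somatic variant allele fraction in tumor and
#'   matched normal reads.
#' @param ct_bias Weight of the canonical C>T (and complementary G>A)
#'   substitution when drawing an alt allele at a C/G reference site.
#' @param gene_design Optional tibble describing per-gene group bias, with
#'   columns `gene` and either exact mutated-sample counts (`mut_primary`,
#'   `mut_recurrent`) or probabilities (`p_primary`, `p_recurrent`). Genes not
#'   listed fall back to `somatic_rate` in both groups. `NULL` uses
#'   [default_gene_design()] applied to the first nine genes.
#' @return A `ss_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       n_duplications = 2L,
                       duplication_length = 500L,
                       n_genes = 20L,
                       gene_length = 2000L,
                       n_primary = 20L,
                       n_recurrent = 17L,
                       mean_depth = 60,
                       base_error_rate = 0.001,
                       base_quality_mean = 30,
                       base_quality_sd = 5,
                       base_quality_range = c(2L, 41L),
                       mapping_quality = 60L,
                       duplication_mq0_prob = 0.5,
                       germline_site_rate = 0.001,
                       germline_het_prob = 0.3,
                       somatic_rate = 0.08,
                       somatic_indel_fraction = 0.15,
                       tumor_vaf = 0.5,
                       normal_vaf = 0,
                       ct_bias = 0.8,
                       gene_design = NULL) {
  probs <- c(base_error_rate, duplication_mq0_prob, germline_site_rate,
             germline_het_prob, somatic_rate, somatic_indel_fraction,
             tumor_vaf, normal_vaf, ct_bias)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1].")
  }
  if (n_primary < 1L || n_recurrent < 1L) abort("group sizes must be >= 1.")
  if (genome_length <= 2L * n_duplications * duplication_length) {
    abort("genome_length must exceed the total duplication span.")
  }
  if (n_genes < 1L) abort("at least one gene interval is required.")
  if (n_genes * gene_length > genome_length) {
    abort("gene intervals do not fit in the genome.")
  }
  structure(list(
    seed = as.integer(seed),
    genome_length = as.integer(genome_length),
    n_duplications = as.integer(n_duplications),
    duplication_length = as.integer(duplication_length),
    n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    n_primary = as.integer(n_primary),
    n_recurrent = as.integer(n_recurrent),
    mean_depth = mean_depth,
    base_error_rate = base_error_rate,
    base_quality_mean = base_quality_mean,
    base_quality_sd = base_quality_sd,
    base_quality_range = as.integer(base_quality_range),
    mapping_quality = as.integer(mapping_quality),
    duplication_mq0_prob = duplication_mq0_prob,
    germline_site_rate = germline_site_rate,
    germline_het_prob = germline_het_prob,
    somatic_rate = somatic_rate,
    somatic_indel_fraction = somatic_indel_fraction,
    tumor_vaf = tumor_vaf,
    normal_vaf = normal_vaf,
    ct_bias = ct_bias,
    gene_design = gene_design
  ), class = "ss_sim_config")
}

#' Full-scale emulated study configuration
#'
#' The cohort conditions used for end-to-end parameter-recovery runs: the
#' 20 primary / 17 recurrent two-group design with the printed per-gene
#' counts ([default_gene_design()]), mean depth 60, somatic VAF 0.5, and a
#' 210 kb reference carrying 40 gene targets of 5 kb (200 kb of target
#' space) plus two exact 500 bp segmental duplications.
#'
#' @param seed Integer seed.
#' @return A `ss_sim_config`.
#' @export
study_config <- function(seed = 1L) {
  sim_config(seed = seed, genome_length = 210000L, n_genes = 40L,
             gene_length = 5000L)
}

#' Default per-gene group-biased mutation design
#'
#' Exact mutated-sample counts for the nine genes whose two-group mutation
#' frequencies the pipeline compares (chromatin modifiers exclusive to one
#' group plus the classic bladder-cancer genes), in a 20-primary /
#' 17-recurrent cohort: MLL, EP400 and PRDM2 mutated in 4/17 recurrent and
#' 0/20 primary samples; MLL3 2/20 and EP300 3/20 primary-only; FGFR3 2/20
#' vs 3/17; HRAS 6/20 vs 1/17; TP53 3/20 vs 4/17; RB1 1/20 vs 2/17.
#'
#' @return Tibble with columns `gene`, `mut_primary`, `mut_recurrent`.
#' @export
default_gene_design <- function() {
  tibble(
    gene = c("MLL", "EP400", "PRDM2", "MLL3", "EP300",
             "FGFR3", "HRAS", "TP53", "RB1"),
    mut_primary = c(0L, 0L, 0L, 2L, 3L, 2L, 6L, 3L, 1L),
    mut_recurrent = c(4L, 4L, 4L, 0L, 0L, 3L, 1L, 4L, 2L)
  )
}

# derive a reproducible sub-seed (< 2^31) from the base seed and a tag
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * (seq_along(utf8ToInt(tag)) + 7L))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a reference genome with exact segmental duplications
#'
#' Draws an i.i.d. uniform ACGT sequence and copies `n_duplications`
#' segments verbatim to distant loci, producing exact duplications that the
#' remappability filter must catch. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character vector, one contig `chr1`),
#'   `duplications` (tibble of 1-based `src_start`, `src_end`, `copy_start`,
#'   `copy_end`), and `targets` (BED-frame gene intervals, see
#'   [simulate_targets()]).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "ss_sim_config"))
  L <- config$genome_length
  dl <- config$duplication_length
  nd <- config$n_duplications
  targets <- simulate_targets(config)
  with_seed(derive_seed(config$seed, "reference"), {
    bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    seq <- paste(bases, collapse = "")
    dups <- tibble(contig = character(0), src_start = integer(0),
                   src_end = integer(0), copy_start = integer(0),
                   copy_end = integer(0))
    if (nd > 0L) {
      # place source/copy pairs inside distinct gene bodies so duplicated
      # targets are exercised by the caller and the remap filter; host them
      # in the trailing (background) genes, away from the named comparison
      # panel whose counts the two-group analysis reproduces
      if (2L * nd > nrow(targets)) {
        abort("duplication placement impossible: not enough gene intervals.")
      }
      if (dl + 2L > config$gene_length) {
        abort("duplication placement impossible: duplication exceeds gene length.")
      }
      host <- rev(seq_len(nrow(targets)))[seq_len(2L * nd)]
      starts <- integer(0)
      for (i in seq_len(nd)) {
        g_src <- targets[host[2L * i - 1L], ]
        g_cp <- targets[host[2L * i], ]
        src_start <- g_src$start + 1L +
          sample.int(config$gene_length - dl, 1L)
        copy_start <- g_cp$start + 1L +
          sample.int(config$gene_length - dl, 1L)
        src_seq <- substr(seq, src_start, src_start + dl - 1L)
        substr(seq, copy_start, copy_start + dl - 1L) <- src_seq
        dups <- bind_rows(dups, tibble(
          contig = "chr1",
          src_start = src_start, src_end = src_start + dl - 1L,
          copy_start = copy_start, copy_end = copy_start + dl - 1L
        ))
      }
    }
    list(genome = c(chr1 = seq), duplications = dups, targets = targets)
  })
}

#' Gene target intervals for a simulated genome
#'
#' Genes are tiled evenly across the contig with uniform intergenic gaps.
#' The first nine genes carry the names of the comparison panel (see
#' [default_gene_design()]); the rest are `G10`, `G11`, ...
#'
#' @param config A [sim_config()].
#' @return Tibble in BED frame: `contig`, `start` (0-based), `end`, `gene`.
#' @export
simulate_targets <- function(config) {
  n <- config$n_genes
  glen <- config$gene_length
  gap <- (config$genome_length - n * glen) %/% (n + 1L)
  start <- gap + (seq_len(n) - 1L) * (glen + gap)
  panel <- default_gene_design()$gene
  gene <- sprintf("G%02d", seq_len(n))
  k <- min(n, length(panel))
  gene[seq_len(k)] <- panel[seq_len(k)]
  tibble(contig = "chr1", start = as.integer(start),
         end = as.integer(start + glen), gene = gene)
}

# draw alt bases for SNVs with the configured C>T/G>A class weight
draw_alt_bases <- function(ref, ct_bias) {
  n <- length(ref)
  alt <- character(n)
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", C = "T", G = "A", T = "C")
  for (i in seq_len(n)) {
    r <- ref[i]
    others <- setdiff(bases, r)
    if (r %in% c("C", "G")) {
      canon <- transition[[r]]  # C>T or G>A
      rest <- setdiff(others, canon)
      w <- c(ct_bias, rep((1 - ct_bias) / 2, 2))
      alt[i] <- sample(c(canon, rest), 1L, prob = w)
    } else {
      alt[i] <- sample(others, 1L)
    }
  }
  alt
}

#' Simulate cohort truth: samples, germline catalog, somatic assignments
#'
#' Builds the cohort design table (`P01..`, `R01..`), a dbSNP-like catalog of
#' polymorphic sites, per-sample heterozygous germline genotypes drawn from
#' the catalog, and per-gene somatic assignments: genes with an explicit
#' design row receive exactly the configured number of mutated samples per
#' group (chosen at random); other genes mutate each sample independently
#' with `somatic_rate`. Each mutated sample gets one somatic variant at a
#' uniformly chosen in-gene position.
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()].
#' @return List with `cohort`, `catalog`, `truth` (per-sample variant
#'   records, `origin` germline/somatic), and `gene_group_truth` (per-gene
#'   mutated-sample counts by group).
#' @export
simulate_truth <- function(config, reference) {
  stopifnot(inherits(config, "ss_sim_config"))
  genome <- reference$genome
  targets <- reference$targets
  cohort <- tibble(
    sample = c(sprintf("P%02d", seq_len(config$n_primary)),
               sprintf("R%02d", seq_len(config$n_recurrent))),
    group = c(rep("primary", config$n_primary),
              rep("recurrent", config$n_recurrent))
  )
  with_seed(derive_seed(config$seed, "truth"), {
    L <- config$genome_length
    seq <- genome[["chr1"]]

    # dbSNP-like catalog of polymorphic sites (SNVs, genome-wide)
    n_cat <- round(L * config$germline_site_rate)
    cat_pos <- if (n_cat > 0L) sort(sample.int(L, n_cat)) else integer(0)
    cat_ref <- if (n_cat > 0L) substring(seq, cat_pos, cat_pos)
               else character(0)
    cat_alt <- draw_alt_bases(cat_ref, ct_bias = 0)
    catalog <- tibble(contig = "chr1", pos = cat_pos, ref = cat_ref,
                      alt = cat_alt, type = "SNV",
                      id = sprintf("rs%06d", seq_len(n_cat)))

    # per-sample heterozygous germline genotypes
    germ <- purrr::map_dfr(cohort$sample, function(s) {
      het <- runif(n_cat) < config$germline_het_prob
      if (!any(het)) return(NULL)
      tibble(sample = s, contig = "chr1", pos = cat_pos[het],
             ref = cat_ref[het], alt = cat_alt[het], type = "SNV",
             gene = NA_character_, origin = "germline")
    })

    # somatic assignment per gene per group
    design <- config$gene_design
    if (is.null(design)) design <- default_gene_design()
    design <- as_tibble(design)
    som <- list()
    for (gi in seq_len(nrow(targets))) {
      g <- targets$gene[gi]
      g_start1 <- targets$start[gi] + 1L
      g_end1 <- targets$end[gi]
      drow <- design[design$gene == g, , drop = FALSE]
      mutated <- character(0)
      for (grp in c("primary", "recurrent")) {
        members <- cohort$sample[cohort$group == grp]
        if (nrow(drow) == 1L && "mut_primary" %in% names(drow) &&
            !is.na(drow[[paste0("mut_", grp)]][1])) {
          k <- drow[[paste0("mut_", grp)]][1]
          if (k > length(members)) {
            abort(paste0("design count exceeds group size for gene ", g))
          }
          mutated <- c(mutated, sample(members, k))
        } else {
          p <- if (nrow(drow) == 1L && paste0("p_", grp) %in% names(drow)) {
            drow[[paste0("p_", grp)]][1]
          } else {
            config$somatic_rate
          }
          mutated <- c(mutated, members[runif(length(members)) < p])
        }
      }
      if (length(mutated) == 0L) next
      for (s in mutated) {
        taken <- c(catalog$pos,
                   if (length(som) > 0L) {
                     tb <- bind_rows(som)
                     tb$pos[tb$sample == s]
                   } else integer(0))
        repeat {
          pos <- g_start1 + sample.int(g_end1 - g_start1 - 3L, 1L)
          if (!pos %in% taken) break
        }
        is_indel <- runif(1) < config$somatic_indel_fraction
        anchor <- substring(seq, pos, pos)
        if (!is_indel) {
          alt <- draw_alt_bases(anchor, config$ct_bias)
          som[[length(som) + 1L]] <- tibble(
            sample = s, contig = "chr1", pos = pos, ref = anchor,
            alt = alt, type = "SNV", gene = g, origin = "somatic")
        } else {
          len <- sample.int(3L, 1L)
          if (runif(1) < 0.5) {
            ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                         collapse = "")
            som[[length(som) + 1L]] <- tibble(
              sample = s, contig = "chr1", pos = pos, ref = anchor,
              alt = paste0(anchor, ins), type = "INS", gene = g,
              origin = "somatic")
          } else {
            delseq <- substring(seq, pos, pos + len)
            som[[length(som) + 1L]] <- tibble(
              sample = s, contig = "chr1", pos = pos, ref = delseq,
              alt = anchor, type = "DEL", gene = g, origin = "somatic")
          }
        }
      }
    }
    somatic <- if (length(som) > 0L) bind_rows(som) else
      tibble(sample = character(0), contig = character(0), pos = integer(0),
             ref = character(0), alt = character(0), type = character(0),
             gene = character(0), origin = character(0))
    truth <- bind_rows(germ, somatic) %>% arrange(.data$sample, .data$pos)

    ggt <- somatic %>%
      distinct(.data$gene, .data$sample) %>%
      left_join(cohort, by = "sample") %>%
      count(.data$gene, .data$group) %>%
      tidyr::pivot_wider(names_from = "group", values_from = "n",
                         values_fill = 0L)
    for (col in c("primary", "recurrent")) {
      if (!col %in% names(ggt)) ggt[[col]] <- 0L
    }
    ggt <- targets %>% select("gene") %>%
      left_join(ggt, by = "gene") %>%
      mutate(primary = tidyr::replace_na(.data$primary, 0L),
             recurrent = tidyr::replace_na(.data$recurrent, 0L),
             n_primary = config$n_primary,
             n_recurrent = config$n_recurrent)

    list(cohort = cohort, catalog = catalog, truth = truth,
         gene_group_truth = ggt)
  })
}

#' Simulate tumor and normal pileups for one sample
#'
#' Per target site, depth is Poisson(`mean_depth`); each read draws the alt
#' allele with probability `tumor_vaf` (tumor) or `normal_vaf` (normal) at
#' that sample's somatic sites and 0.5 at heterozygous germline sites (both
#' tissues); substitution sequencing errors replace the drawn base with a
#' uniform different base at `base_error_rate`; base qualities follow the
#' clamped Normal model; mapping quality is `mapping_quality` except inside
#' duplications, where reads drop to 0 with `duplication_mq0_prob`.
#' Deterministic given (config seed, sample id).
#'
#' @param reference Output of [simulate_reference()].
#' @param truth Truth table for this sample (rows of `simulate_truth()$truth`).
#' @param config A [sim_config()].
#' @param sample_id Sample identifier (enters the RNG stream derivation).
#' @param sparse When `TRUE`, per-read rows are emitted only for
#'   non-reference observations, and the site table carries the exact mean
#'   base quality of all reads at each site; reference-matching reads are
#'   otherwise not materialized. Candidate calling consumes either form and
#'   produces identical support statistics; sparse pileups cannot be
#'   serialized with [write_pileup()].
#' @return List with `tumor` and `normal` `ss_pileup` objects.
#' @export
simulate_sample_pileups <- function(reference, truth, config, sample_id,
                                    sparse = FALSE) {
  stopifnot(inherits(config, "ss_sim_config"))
  genome <- reference$genome
  targets <- reference$targets
  seq <- genome[["chr1"]]
  L <- nchar(seq)
  if (nrow(truth) > 0L && any(truth$pos < 1L | truth$pos > L)) {
    abort("truth variant outside reference bounds.")
  }
  pos <- unlist(purrr::map2(targets$start + 1L, targets$end, seq.int))
  refc <- substring(seq, pos, pos)
  n_sites <- length(pos)

  in_dup <- rep(FALSE, n_sites)
  if (nrow(reference$duplications) > 0L) {
    for (i in seq_len(nrow(reference$duplications))) {
      d <- reference$duplications[i, ]
      in_dup <- in_dup | (pos >= d$src_start & pos <= d$src_end) |
        (pos >= d$copy_start & pos <= d$copy_end)
    }
  }

  # per-site event maps for this sample
  site_idx_of <- function(p) match(p, pos)
  som <- truth[truth$origin == "somatic", , drop = FALSE]
  germ <- truth[truth$origin == "germline", , drop = FALSE]

  af_t <- numeric(n_sites)
  af_n <- numeric(n_sites)
  ev_type <- rep(NA_character_, n_sites)   # SNV/INS/DEL at the site
  ev_allele <- rep(NA_character_, n_sites) # snv alt base, "+SEQ", "-N"
  if (nrow(germ) > 0L) {
    gi <- site_idx_of(germ$pos)
    keep <- !is.na(gi)
    af_t[gi[keep]] <- 0.5
    af_n[gi[keep]] <- 0.5
    ev_type[gi[keep]] <- "SNV"
    ev_allele[gi[keep]] <- germ$alt[keep]
  }
  if (nrow(som) > 0L) {
    si <- site_idx_of(som$pos)
    keep <- !is.na(si)
    af_t[si[keep]] <- config$tumor_vaf
    af_n[si[keep]] <- config$normal_vaf
    ev_type[si[keep]] <- som$type[keep]
    ev_allele[si[keep]] <- dplyr::case_when(
      som$type[keep] == "SNV" ~ som$alt[keep],
      som$type[keep] == "INS" ~ paste0("+", substring(som$alt[keep], 2L)),
      som$type[keep] == "DEL" ~ paste0("-", nchar(som$ref[keep]) - 1L)
    )
  }

  bases4 <- c("A", "C", "G", "T")
  refcode_site <- match(refc, bases4)

  ev_site <- which(!is.na(ev_type))
  dup_site <- which(in_dup)

  # Each tissue draws from its own derived stream; the draws shared by the
  # sparse and full representations come first, and the full form's bulk
  # strand/mapping-quality draws (which never enter support statistics) come
  # from a further derived stream, so both forms yield identical candidate
  # statistics for the same seed.
  gen_tissue <- function(af, sparse, tag) {
    set.seed(derive_seed(config$seed,
                         paste0("pileup:", sample_id, ":", tag)))
    depth <- rpois(n_sites, config$mean_depth)
    N <- sum(depth)
    offset <- cumsum(depth) - depth  # reads of site i: offset[i] + 1:depth[i]

    # base qualities for every read (site-level means are exact)
    bq <- as.integer(round(rnorm(N, config$base_quality_mean,
                                 config$base_quality_sd)))
    bq[bq < config$base_quality_range[1]] <- config$base_quality_range[1]
    bq[bq > config$base_quality_range[2]] <- config$base_quality_range[2]

    # allele draws only at this sample's event sites (indexed directly, the
    # bulk of reads is never scanned)
    ev_idx <- ev_site[af[ev_site] > 0]
    rd_ev <- sequence(depth[ev_idx]) + rep.int(offset[ev_idx], depth[ev_idx])
    ev_of_rd <- rep.int(ev_idx, depth[ev_idx])
    is_alt <- runif(length(rd_ev)) < af[ev_of_rd]
    alt_rd <- rd_ev[is_alt]
    alt_site <- ev_of_rd[is_alt]
    is_snv_ev <- ev_type[alt_site] == "SNV"
    snv_rd <- alt_rd[is_snv_ev]
    snv_code <- match(ev_allele[alt_site[is_snv_ev]], bases4)
    indel_rd <- alt_rd[!is_snv_ev]
    indel_allele <- ev_allele[alt_site[!is_snv_ev]]

    # substitution sequencing errors on non-indel reads, by count then index
    n_err <- rbinom(1L, N, config$base_error_rate)
    err <- if (n_err > 0L) setdiff(sample.int(N, n_err), indel_rd)
           else integer(0)

    site_of <- function(rd) findInterval(rd, offset + 1L)
    touched <- unique(c(snv_rd, err))
    ref_tu <- refcode_site[site_of(touched)]
    code_tu <- ref_tu
    code_tu[match(snv_rd, touched)] <- snv_code
    if (length(err) > 0L) {
      me <- match(err, touched)
      shift <- sample.int(3L, length(err), replace = TRUE)
      code_tu[me] <- ((code_tu[me] - 1L + shift) %% 4L) + 1L
    }
    is_snv <- code_tu != ref_tu
    snv_idx <- touched[is_snv]
    snv_allele <- bases4[code_tu[is_snv]]

    # rows that need per-read detail: non-reference observations
    det <- c(snv_idx, indel_rd)
    det_call <- c(rep.int("snv", length(snv_idx)),
                  ifelse(startsWith(indel_allele, "+"), "ins", "del"))
    det_allele <- c(snv_allele, indel_allele)
    o <- order(det)
    det <- det[o]; det_call <- det_call[o]; det_allele <- det_allele[o]
    det_site <- site_of(det)

    det_mq <- rep.int(config$mapping_quality, length(det))
    det_strand <- c("+", "-")[sample.int(2L, length(det), replace = TRUE)]
    in_dup_det <- in_dup[det_site]
    det_mq[in_dup_det &
             runif(length(det)) < config$duplication_mq0_prob] <- 0L

    if (sparse) {
      # site-level mean base quality stands in for the reference reads
      sums <- rowsum(bq, rep.int(seq_len(n_sites), depth), reorder = FALSE)
      covered <- depth > 0L
      mean_bq <- numeric(n_sites)
      mean_bq[covered] <- as.numeric(sums) / depth[covered]
      reads <- tibble(contig = "chr1", pos = pos[det_site],
                      ref = refc[det_site], call = det_call,
                      allele = det_allele, strand = det_strand,
                      baseq = bq[det], mapq = det_mq)
      sites <- tibble(contig = "chr1", pos = pos, ref = refc, depth = depth,
                      mean_bq = mean_bq)
      out <- pileup_tbl(reads, sites)
      attr(out, "sparse") <- TRUE
      out
    } else {
      set.seed(derive_seed(config$seed,
                           paste0("pileup-bulk:", sample_id, ":", tag)))
      site_r <- rep.int(seq_len(n_sites), depth)
      call <- rep.int("ref", N)
      allele <- rep.int(NA_character_, N)
      call[det] <- det_call
      allele[det] <- det_allele
      mq <- rep.int(config$mapping_quality, N)
      if (length(dup_site) > 0L) {
        rd_dup <- sequence(depth[dup_site]) +
          rep.int(offset[dup_site], depth[dup_site])
        mq0 <- rd_dup[runif(length(rd_dup)) < config$duplication_mq0_prob]
        mq[mq0] <- 0L
      }
      mq[det] <- det_mq
      strand <- c("+", "-")[sample.int(2L, N, replace = TRUE)]
      strand[det] <- det_strand
      reads <- tibble(contig = "chr1", pos = pos[site_r], ref = refc[site_r],
                      call = call, allele = allele, strand = strand,
                      baseq = bq, mapq = mq)
      sites <- tibble(contig = "chr1", pos = pos, ref = refc, depth = depth)
      pileup_tbl(reads, sites)
    }
  }

  with_seed(derive_seed(config$seed, paste0("pileup:", sample_id)), {
    tumor <- gen_tissue(af_t, sparse, "tumor")
    normal <- gen_tissue(af_n, sparse, "normal")
    list(tumor = tumor, normal = normal)
  })
}

#' Simulate a full two-group cohort
#'
#' Convenience wrapper building reference, targets, cohort design, germline
#' catalog and truth set in one deterministic call. Pileups are generated on
#' demand per sample with [simulate_sample_pileups()] (or all at once by
#' [write_cohort()] / [run_pipeline()]), so the cohort object stays small.
#'
#' @param config A [sim_config()].
#' @return A `ss_cohort` list: `config`, `reference` (genome + duplications),
#'   `targets`, `cohort`, `catalog`, `truth`, `gene_group_truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  reference <- simulate_reference(config)
  tr <- simulate_truth(config, reference)
  structure(list(
    config = config,
    reference = reference,
    targets = reference$targets,
    cohort = tr$cohort,
    catalog = tr$catalog,
    truth = tr$truth,
    gene_group_truth = tr$gene_group_truth
  ), class = "ss_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits the reference FASTA, targets BED, cohort TSV, dbSNP-like catalog
#' VCF, per-sample truth VCFs and per-sample tumor/normal pileups under
#' `dir`. Fully deterministic given the cohort's config.
#'
#' @param cohort A `ss_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ss_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pileups"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_reference_fasta(cohort$reference$genome,
                        file.path(dir, "reference.fa"))
  write_bed_intervals(cohort$targets, file.path(dir, "targets.bed"))
  write_cohort_tsv(cohort$cohort, file.path(dir, "cohort.tsv"))
  write_vcf(cohort$catalog, file.path(dir, "dbsnp.vcf"))
  for (s in cohort$cohort$sample) {
    tr <- cohort$truth[cohort$truth$sample == s, , drop = FALSE]
    write_vcf(tr %>% rename(sample_id = "sample"),
              file.path(dir, "truth", paste0(s, ".truth.vcf")))
    pu <- simulate_sample_pileups(cohort$reference, tr, cohort$config, s)
    write_pileup(pu$tumor,
                 file.path(dir, "pileups", paste0(s, ".tumor.pileup")))
    write_pileup(pu$normal,
                 file.path(dir, "pileups", paste0(s, ".normal.pileup")))
  }
  invisible(dir)
}
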