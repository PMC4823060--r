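# Simulated-read remappability filter for pseudo-gene / segmental-duplication
# artifacts: tile error-free reads across the variant haplotype, place each
# read back on the reference on both strands, and discard the variant when
# more than the allowed fraction of its reads cannot be placed uniquely.
#
# Placement model: a placement is a start offset on a strand of a contig; its
# distance is the Hamming distance for substitution-only reads, and for
# indel-containing reads the minimum Levenshtein distance to reference
# windows of length read_length +/- band_width starting at that offset. A
# read is uniquely mapped iff exactly one placement attains the minimal
# distance and that distance is within max_edit_distance; tied minima are
# ambiguous, and minima beyond the bound are unmapped. Candidate placements
# are seeded with Biostrings approximate matching and re-scored exactly, so
# verdicts match an exhaustive per-offset scan.

#' Remappability filter configuration
#'
#' @param read_length Simulated read length (bases).
#' @param max_ambiguous_fraction Discard bound: a variant is discarded iff
#'   the fraction of non-uniquely-mapped reads strictly exceeds this value.
#' @param max_edit_distance Maximum distance for a placement to count as
#'   mapped.
#' @param band_width Window-length slack (bases) for indel-containing reads.
#' @return A `ss_remap_config` list.
#' @export
remap_config <- function(read_length = 80L,
                         max_ambiguous_fraction = 0.10,
                         max_edit_distance = 4L,
                         band_width = 5L) {
  if (read_length < 1L) abort("read_length must be >= 1.")
  if (max_ambiguous_fraction < 0 || max_ambiguous_fraction > 1) {
    abort("max_ambiguous_fraction must lie in [0, 1].")
  }
  structure(list(read_length = as.integer(read_length),
                 max_ambiguous_fraction = max_ambiguous_fraction,
                 max_edit_distance = as.integer(max_edit_distance),
                 band_width = as.integer(band_width)),
            class = "ss_remap_config")
}

#' Generate variant-containing simulated reads
#'
#' Applies the variant to its contig to build the alternate haplotype and
#' emits every `read_length` window of that haplotype covering at least one
#' edited base (for deletions, the junction), clipped at contig ends. Reads
#' are error-free.
#'
#' @param variant One-row tibble (or list) with `contig`, `pos`, `ref`,
#'   `alt`, `type`.
#' @param reference Named character vector of contig sequences.
#' @param config A [remap_config()].
#' @return Tibble with columns `seq` and `origin` (window start on the
#'   alternate haplotype, 1-based).
#' @export
generate_variant_reads <- function(variant, reference, config = remap_config()) {
  v <- as.list(variant)
  L <- config$read_length
  ctg <- reference[[v$contig]]
  if (is.null(ctg)) abort(paste0("unknown contig: ", v$contig))
  if (nchar(ctg) < L) abort("contig shorter than the read length.")
  p <- v$pos
  type <- v$type
  if (ref_seq(reference, v$contig, p, p + nchar(v$ref) - 1L) != v$ref) {
    abort("variant ref allele disagrees with the reference.")
  }
  if (type == "SNV") {
    hap <- ctg
    substr(hap, p, p) <- v$alt
    first_edit <- p
    last_edit <- p
  } else if (type == "INS") {
    ins <- substring(v$alt, 2L)
    hap <- paste0(substr(ctg, 1L, p), ins,
                  substr(ctg, p + 1L, nchar(ctg)))
    first_edit <- p + 1L
    last_edit <- p + nchar(ins)
  } else if (type == "DEL") {
    dlen <- nchar(v$ref) - 1L
    hap <- paste0(substr(ctg, 1L, p),
                  substr(ctg, p + dlen + 1L, nchar(ctg)))
    # junction: windows must contain haplotype positions p and p+1
    first_edit <- p + 1L
    last_edit <- p
  } else {
    abort(paste0("unknown variant type: ", type))
  }
  nh <- nchar(hap)
  lo <- max(1L, first_edit - L + 1L)
  hi <- min(last_edit, nh - L + 1L)
  if (lo > hi) {
    abort("no reads can be generated for this variant (degenerate contig).")
  }
  starts <- seq.int(lo, hi)
  tibble(seq = substring(hap, starts, starts + L - 1L),
         origin = as.integer(starts))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# exact per-offset distances at given starts on one contig string
placement_distances <- function(read, contig_seq, starts, has_indel,
                                band_width) {
  L <- nchar(read)
  clen <- nchar(contig_seq)
  starts <- starts[starts >= 1L & starts <= clen - L + 1L]
  if (length(starts) == 0L) {
    return(tibble(start = integer(0), dist = integer(0)))
  }
  if (!has_indel) {
    windows <- substring(contig_seq, starts, starts + L - 1L)
    rchars <- strsplit(read, "", fixed = TRUE)[[1]]
    wchars <- strsplit(windows, "", fixed = TRUE)
    dist <- vapply(wchars, function(w) sum(w != rchars), integer(1))
  } else {
    dist <- vapply(starts, function(s) {
      lo <- max(1L, L - band_width)
      hi <- min(L + band_width, clen - s + 1L)
      if (hi < lo) return(NA_real_)
      lens <- seq.int(lo, hi)
      wins <- substring(contig_seq, s, s + lens - 1L)
      min(utils::adist(read, wins))
    }, numeric(1))
    keep <- !is.na(dist)
    starts <- starts[keep]
    dist <- as.integer(dist[keep])
  }
  tibble(start = starts, dist = dist)
}

#' Classify the placement of one simulated read
#'
#' Scores candidate placements of `read` on both strands of every contig and
#' returns `"unique"` (exactly one minimal placement within
#' `max_edit_distance`), `"ambiguous"` (tied minimal placements) or
#' `"unmapped"` (no placement within the bound).
#'
#' @param read Read sequence (character scalar).
#' @param reference Named character vector of contig sequences.
#' @param config A [remap_config()].
#' @param has_indel Whether the read spans an indel edit (switches the
#'   scorer from Hamming to banded Levenshtein distance).
#' @param subjects Optional precomputed list of `DNAString` subjects (one
#'   per contig), to avoid rebuilding them per read.
#' @return List with `verdict`, `contig`, `position`, `strand`, `distance`
#'   (`NA` placement fields unless unique).
#' @export
map_read_unique <- function(read, reference, config = remap_config(),
                            has_indel = FALSE, subjects = NULL) {
  stopifnot(nzchar(read))
  k <- config$max_edit_distance
  bw <- config$band_width
  if (is.null(subjects)) {
    subjects <- lapply(as.list(reference), Biostrings::DNAString)
  }
  hits <- list()
  for (ctg in names(reference)) {
    subj <- subjects[[ctg]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") read else revcomp(read)
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = k,
                                    with.indels = has_indel)
      if (length(m) == 0L) next
      starts <- BiocGenerics::start(m)
      if (has_indel) {
        starts <- unique(unlist(lapply(starts, function(s) {
          seq.int(s - bw, s + bw)
        })))
      }
      d <- placement_distances(pat, reference[[ctg]], unique(starts),
                               has_indel, bw)
      if (nrow(d) == 0L) next
      hits[[length(hits) + 1L]] <- d %>%
        mutate(contig = ctg, strand = strand)
    }
  }
  if (length(hits) == 0L) {
    return(list(verdict = "unmapped", contig = NA_character_,
                position = NA_integer_, strand = NA_character_,
                distance = NA_integer_))
  }
  all_hits <- bind_rows(hits)
  dmin <- min(all_hits$dist)
  if (dmin > k) {
    return(list(verdict = "unmapped", contig = NA_character_,
                position = NA_integer_, strand = NA_character_,
                distance = NA_integer_))
  }
  best <- all_hits %>% filter(.data$dist == dmin)
  if (nrow(best) == 1L) {
    list(verdict = "unique", contig = best$contig, position = best$start,
         strand = best$strand, distance = dmin)
  } else {
    list(verdict = "ambiguous", contig = NA_character_,
         position = NA_integer_, strand = NA_character_, distance = dmin)
  }
}

# hamming distance between two equal-length strings
hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Precompute the reference k-mer index for the remappability filter
#'
#' Tabulates every half-read-length window of each contig so that the
#' seed-and-verify fast path can locate exact seed matches with one hash
#' lookup pass per variant. Build it once and pass it to [remap_filter()] /
#' [run_filter_cascade()] when filtering many variants against the same
#' reference.
#'
#' @param reference Named character vector of contig sequences.
#' @param config A [remap_config()].
#' @return A `ss_remap_index` list.
#' @export
remap_index <- function(reference, config = remap_config()) {
  L <- config$read_length
  h <- L %/% 2
  widths <- unique(c(h, L - h))
  kmers <- lapply(setNames(widths, widths), function(w) {
    lapply(reference, function(s) {
      n <- nchar(s)
      if (n < w) character(0) else substring(s, 1:(n - w + 1L), w:n)
    })
  })
  structure(list(kmers = kmers, read_length = L),
            class = "ss_remap_index")
}

# Seed-and-verify read classification for a substitution variant. Every
# placement whose distance can matter (<= the origin distance of 1, since
# the origin placement mismatches only at the variant base) contains one
# exactly matching read half; exact matches of all half-windows are found
# against the precomputed k-mer index and re-scored by Hamming distance.
# Verdict-equivalent to map_read_unique(): placements at distance >= 2 can
# neither attain nor tie the minimum.
remap_snv_verdicts <- function(variant, reference, config, index) {
  reads <- generate_variant_reads(variant, reference, config)
  L <- config$read_length
  h <- L %/% 2
  n_reads <- nrow(reads)
  seqs <- reads$seq

  # queries: each read's two halves, forward and reverse-complemented,
  # deduplicated by sequence
  half1 <- substr(seqs, 1L, h)
  half2 <- substr(seqs, h + 1L, L)
  qry <- tibble(
    seq = c(half1, half2),
    read = c(seq_len(n_reads), seq_len(n_reads)),
    off = c(rep(0L, n_reads), rep(h, n_reads)),
    w = c(rep(h, n_reads), rep(L - h, n_reads))
  )
  rc <- qry
  rc$seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rc$seq)))
  qry$strand <- "+"
  rc$strand <- "-"
  qry <- bind_rows(qry, rc)

  placements <- vector("list", n_reads)
  add_placement <- function(rd, ctg, strand, o) {
    placements[[rd]] <<- c(placements[[rd]], paste(ctg, strand, o))
  }
  for (w in unique(qry$w)) {
    qw <- qry[qry$w == w, , drop = FALSE]
    qsplit <- split(seq_len(nrow(qw)), qw$seq)
    qseqs <- names(qsplit)
    for (ctg in names(reference)) {
      km <- index$kmers[[as.character(w)]][[ctg]]
      m <- match(km, qseqs)
      hit_pos <- which(!is.na(m))
      for (gpos in hit_pos) {
        for (qi in qsplit[[m[gpos]]]) {
          rd <- qw$read[qi]
          off <- qw$off[qi]
          o <- if (qw$strand[qi] == "+") gpos - off
               else gpos - (L - off - w)
          add_placement(rd, ctg, qw$strand[qi], o)
        }
      }
    }
  }

  rc_reads <- character(n_reads)
  verdicts <- character(n_reads)
  for (rd in seq_len(n_reads)) {
    pls <- unique(placements[[rd]])
    dists <- integer(0)
    for (pl in pls) {
      parts <- strsplit(pl, " ", fixed = TRUE)[[1]]
      ctg <- parts[1]; strand <- parts[2]; o <- as.integer(parts[3])
      clen <- nchar(reference[[ctg]])
      if (o < 1L || o + L - 1L > clen) next
      pat <- if (strand == "+") seqs[rd] else {
        if (!nzchar(rc_reads[rd])) rc_reads[rd] <- revcomp(seqs[rd])
        rc_reads[rd]
      }
      dists <- c(dists, hamming(pat, substr(reference[[ctg]], o, o + L - 1L)))
    }
    relevant <- dists[dists <= 1L]
    verdicts[rd] <- if (length(relevant) == 0L) "unmapped"
      else if (sum(relevant == min(relevant)) == 1L) "unique"
      else "ambiguous"
  }
  verdicts
}

#' Remappability filter over a variant table
#'
#' For each variant, generates the tiled simulated reads, classifies every
#' read's placement, and computes the ambiguous fraction
#' `(#ambiguous + #unmapped) / #reads`. The variant is discarded iff the
#' fraction strictly exceeds `max_ambiguous_fraction`. Substitution reads
#' are classified with an exact seed-and-verify scheme (one dictionary match
#' pass per variant); indel-containing reads go through [map_read_unique()]
#' read by read. Both routes are verdict-equivalent to the exhaustive
#' per-offset scan.
#'
#' @param variants Tibble with `contig`, `pos`, `ref`, `alt`, `type`.
#' @param reference Named character vector of contig sequences.
#' @param config A [remap_config()].
#' @param index Optional precomputed [remap_index()] for `reference`.
#' @return `variants` with columns `rmf` (ambiguous fraction) and
#'   `remap_keep` (logical).
#' @export
remap_filter <- function(variants, reference, config = remap_config(),
                         index = NULL) {
  v <- as_tibble(variants)
  n <- nrow(v)
  rmf <- numeric(n)
  if (is.null(index) && any(v$type == "SNV")) {
    index <- remap_index(reference, config)
  }
  subjects <- lapply(as.list(reference), Biostrings::DNAString)
  for (i in seq_len(n)) {
    if (v$type[i] == "SNV") {
      verdicts <- remap_snv_verdicts(v[i, ], reference, config, index)
    } else {
      reads <- generate_variant_reads(v[i, ], reference, config)
      # the origin placement costs at most the indel length, so a tighter
      # acceptance bound is equivalent and cheaper
      d_origin <- abs(nchar(v$ref[i]) - nchar(v$alt[i]))
      cfg_i <- config
      cfg_i$max_edit_distance <- min(config$max_edit_distance, d_origin)
      verdicts <- vapply(reads$seq, function(r) {
        map_read_unique(r, reference, cfg_i, has_indel = TRUE,
                        subjects = subjects)$verdict
      }, character(1), USE.NAMES = FALSE)
    }
    rmf[i] <- mean(verdicts != "unique")
  }
  v$rmf <- rmf
  v$remap_keep <- rmf <= config$max_ambiguous_fraction
  v
}
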