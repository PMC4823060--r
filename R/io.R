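# Text-format I/O: FASTA references, samtools-mpileup-style pileups (7-column
# dialect with per-read mapping qualities), minimal 8-column VCF, BED4 target
# intervals, and cohort TSV.
#
# Conventions: positions are 1-based inside the package (the native
# R/Bioconductor frame); BED keeps its own 0-based half-open coordinates on
# read/write and is converted at the point of use.

VALID_BASES <- c("A", "C", "G", "T", "N")

# ---------------------------------------------------------------------------
# Reference FASTA

#' Read a reference genome from FASTA
#'
#' Reads a (possibly multi-line) FASTA file into a named character vector of
#' upper-case sequences, one element per contig. Contig names must be unique
#' and non-empty, sequences non-empty and restricted to `A C G T N`
#' (case-insensitive).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case contig sequences.
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- names(ss)
  # drop anything after first whitespace in the header, FASTA-style
  nm <- sub("\\s.*$", "", nm)
  if (any(!nzchar(nm))) {
    abort("FASTA contains a contig with an empty name.")
  }
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate FASTA header: ", nm[duplicated(nm)][1]))
  }
  seqs <- toupper(as.character(ss))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(paste0("empty sequence for contig: ", nm[empty][1]))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("contig ", nm[bad][1],
                 " contains characters outside {A,C,G,T,N}."))
  }
  setNames(seqs, nm)
}

#' Write a reference genome to FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(genome, path, width = 70L) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  ss <- Biostrings::DNAStringSet(toupper(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Extract a subsequence from a reference genome
#'
#' 1-based inclusive lookup; errors when the contig is unknown or the range
#' falls outside the contig.
#'
#' @param genome Named character vector of contig sequences.
#' @param contig Contig name.
#' @param start,end 1-based inclusive bounds.
#' @return Character scalar.
#' @export
ref_seq <- function(genome, contig, start, end = start) {
  if (!contig %in% names(genome)) {
    abort(paste0("unknown contig: ", contig))
  }
  len <- nchar(genome[[contig]])
  if (any(start < 1L) || any(end > len) || any(end < start)) {
    abort(paste0("position out of bounds for contig ", contig,
                 " (length ", len, ")"))
  }
  substr(rep(genome[[contig]], length(start)), start, end)
}

# ---------------------------------------------------------------------------
# Pileup (samtools mpileup text dialect, 7 columns)

#' Construct a pileup object
#'
#' A pileup is a tibble of per-read observations (one row per read per site)
#' carrying a `sites` attribute: a site-level tibble with the declared depth
#' at every covered position (including zero-depth positions, which have no
#' read rows).
#'
#' @param reads Tibble with columns `contig`, `pos`, `ref`, `call`
#'   (one of `"ref"`, `"snv"`, `"ins"`, `"del"`, `"gap"`), `allele`
#'   (`NA` for ref/gap, alt base for snv, `"+SEQ"` for insertions,
#'   `"-N"` for deletions), `strand` (`"+"`/`"-"`), `baseq`, `mapq`.
#' @param sites Tibble with columns `contig`, `pos`, `ref`, `depth`.
#' @return A `ss_pileup` tibble.
#' @export
pileup_tbl <- function(reads, sites) {
  out <- as_tibble(reads)
  attr(out, "sites") <- as_tibble(sites)
  class(out) <- c("ss_pileup", class(out))
  out
}

#' Site-level depth table of a pileup
#'
#' @param pileup A `ss_pileup` object.
#' @return Tibble with columns `contig`, `pos`, `ref`, `depth`.
#' @export
pileup_sites <- function(pileup) {
  s <- attr(pileup, "sites")
  if (is.null(s)) {
    abort("not a pileup object (missing sites attribute).")
  }
  s
}

# scanner for pileup base strings containing meta-characters; returns a list
# of equal-length vectors (call, allele, strand)
scan_pileup_bases <- function(bases, ref, line_no) {
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  nch <- length(chars)
  call <- character(0)
  allele <- character(0)
  strand <- character(0)
  i <- 1L
  err <- function(msg) {
    abort(paste0("pileup format error at line ", line_no, ": ", msg))
  }
  while (i <= nch) {
    ch <- chars[i]
    if (ch == "^") {
      if (i + 1L > nch) err("'^' at end of base string")
      i <- i + 2L  # '^' consumes the following mapping-quality character
      next
    }
    if (ch == "$") {
      i <- i + 1L
      next
    }
    if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= nch && chars[j] >= "0" && chars[j] <= "9") j <- j + 1L
      if (j == i + 1L) err(paste0("'", ch, "' not followed by a length"))
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      if (j + len - 1L > nch) err("indel sequence truncated")
      seq <- toupper(paste(chars[j:(j + len - 1L)], collapse = ""))
      if (grepl("[^ACGTN]", seq)) err("indel sequence has invalid bases")
      k <- length(call)
      if (k == 0L) err(paste0("'", ch, "' with no preceding read"))
      if (call[k] %in% c("ins", "del")) err("two indel events on one read")
      if (ch == "+") {
        call[k] <- "ins"
        allele[k] <- paste0("+", seq)
      } else {
        call[k] <- "del"
        allele[k] <- paste0("-", len)
      }
      i <- j + len
      next
    }
    if (ch == ".") {
      call <- c(call, "ref"); allele <- c(allele, NA_character_)
      strand <- c(strand, "+")
    } else if (ch == ",") {
      call <- c(call, "ref"); allele <- c(allele, NA_character_)
      strand <- c(strand, "-")
    } else if (ch == "*") {
      call <- c(call, "gap"); allele <- c(allele, NA_character_)
      strand <- c(strand, "+")
    } else if (toupper(ch) %in% VALID_BASES) {
      up <- toupper(ch)
      if (up == ref) err(paste0("explicit base call '", ch,
                                "' equals the reference base"))
      call <- c(call, "snv"); allele <- c(allele, up)
      strand <- c(strand, if (ch == up) "+" else "-")
    } else {
      err(paste0("unknown character '", ch, "' in base string"))
    }
    i <- i + 1L
  }
  list(call = call, allele = allele, strand = strand)
}

# decode one Phred+33 quality string into integer qualities
decode_phred <- function(s) {
  if (!nzchar(s)) return(integer(0))
  utf8ToInt(s) - 33L
}

parse_pileup_lines <- function(lines, line_offset = 0L) {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    empty <- tibble(contig = character(0), pos = integer(0),
                    ref = character(0), call = character(0),
                    allele = character(0), strand = character(0),
                    baseq = integer(0), mapq = integer(0))
    return(pileup_tbl(empty, tibble(contig = character(0), pos = integer(0),
                                    ref = character(0), depth = integer(0))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 7L)) {
    bad <- which(nf < 7L)[1]
    abort(paste0("pileup format error at line ", bad + line_offset,
                 ": expected >= 7 tab-separated fields (7-column mpileup ",
                 "dialect with mapping qualities), found ", nf[bad], "."))
  }
  fm <- matrix(unlist(lapply(fields, `[`, 1:7)), ncol = 7L, byrow = TRUE)
  contig <- fm[, 1]
  pos <- suppressWarnings(as.integer(fm[, 2]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    abort(paste0("pileup format error at line ", bad + line_offset,
                 ": non-integer position '", fm[bad, 2], "'."))
  }
  ref <- toupper(fm[, 3])
  depth <- suppressWarnings(as.integer(fm[, 4]))
  if (anyNA(depth)) {
    bad <- which(is.na(depth))[1]
    abort(paste0("pileup format error at line ", bad + line_offset,
                 ": non-integer depth '", fm[bad, 4], "'."))
  }
  bases <- fm[, 5]
  bq <- fm[, 6]
  mq <- fm[, 7]
  # zero-depth sites are carried in `sites` only; samtools prints '*' fields
  zero <- depth == 0L
  bases[zero] <- ""
  bq[zero] <- ""
  mq[zero] <- ""
  bq[bq == "*"] <- ""
  mq[mq == "*"] <- ""

  nbq <- nchar(bq)
  nmq <- nchar(mq)
  bad_q <- which(nbq != depth | nmq != depth)
  if (length(bad_q) > 0L) {
    b <- bad_q[1]
    abort(paste0("pileup format error at line ", b + line_offset,
                 ": declared depth ", depth[b], " does not match quality ",
                 "string lengths (", nbq[b], ", ", nmq[b], ")."))
  }

  # fast path: base strings free of meta-characters (one char per read)
  special <- grepl("[\\^$+-]", bases)
  call <- vector("list", length(lines))
  allele <- vector("list", length(lines))
  strand <- vector("list", length(lines))

  if (any(!special)) {
    idx <- which(!special)
    cc <- strsplit(bases[idx], "", fixed = TRUE)
    nobs <- lengths(cc)
    mismatch <- nobs != depth[idx]
    if (any(mismatch)) {
      b <- idx[which(mismatch)[1]]
      abort(paste0("pileup format error at line ", b + line_offset,
                   ": declared depth ", depth[b], " does not match ",
                   nchar(bases[b]), " observations."))
    }
    flat <- unlist(cc, use.names = FALSE)
    if (length(flat) > 0L) {
      up <- toupper(flat)
      ref_flat <- rep(ref[idx], nobs)
      is_ref <- flat == "." | flat == ","
      is_gap <- flat == "*"
      is_base <- !is_ref & !is_gap & up %in% VALID_BASES
      unknown <- !is_ref & !is_gap & !is_base
      if (any(unknown)) {
        line_of <- rep(idx, nobs)
        b <- line_of[which(unknown)[1]]
        abort(paste0("pileup format error at line ", b + line_offset,
                     ": unknown character '", flat[which(unknown)[1]],
                     "' in base string."))
      }
      if (any(is_base & up == ref_flat)) {
        line_of <- rep(idx, nobs)
        b <- line_of[which(is_base & up == ref_flat)[1]]
        abort(paste0("pileup format error at line ", b + line_offset,
                     ": explicit base call equals the reference base."))
      }
      fcall <- ifelse(is_ref, "ref", ifelse(is_gap, "gap", "snv"))
      fallele <- ifelse(is_base, up, NA_character_)
      fstrand <- ifelse(flat == "," | (is_base & flat != up), "-", "+")
      split_f <- rep(seq_along(idx), nobs)
      call[idx] <- split(fcall, factor(split_f, levels = seq_along(idx)))
      allele[idx] <- split(fallele, factor(split_f, levels = seq_along(idx)))
      strand[idx] <- split(fstrand, factor(split_f, levels = seq_along(idx)))
    } else {
      call[idx] <- list(character(0))
      allele[idx] <- list(character(0))
      strand[idx] <- list(character(0))
    }
  }
  for (b in which(special)) {
    sc <- scan_pileup_bases(bases[b], ref[b], b + line_offset)
    if (length(sc$call) != depth[b]) {
      abort(paste0("pileup format error at line ", b + line_offset,
                   ": declared depth ", depth[b], " does not match ",
                   length(sc$call), " observations."))
    }
    call[[b]] <- sc$call
    allele[[b]] <- sc$allele
    strand[[b]] <- sc$strand
  }
  for (b in seq_along(lines)) {
    if (is.null(call[[b]])) {
      call[[b]] <- character(0)
      allele[[b]] <- character(0)
      strand[[b]] <- character(0)
    }
  }

  baseq_all <- decode_phred(paste(bq, collapse = ""))
  mapq_all <- decode_phred(paste(mq, collapse = ""))
  reads <- tibble(
    contig = rep(contig, depth),
    pos = rep(pos, depth),
    ref = rep(ref, depth),
    call = unlist(call, use.names = FALSE),
    allele = unlist(allele, use.names = FALSE),
    strand = unlist(strand, use.names = FALSE),
    baseq = baseq_all,
    mapq = mapq_all
  )
  sites <- tibble(contig = contig, pos = pos, ref = ref, depth = depth)
  pileup_tbl(reads, sites)
}

#' Parse a single pileup record
#'
#' Parses one line of 7-column samtools-mpileup-style text (contig, position,
#' reference base, depth, base string, Phred+33 base qualities, Phred+33
#' mapping qualities) into per-read observations. `^` consumes the following
#' character, `$` is consumed silently, `+n<seq>`/`-n<seq>` attach to the
#' preceding read as insertion/deletion, and `*` is a gap observation.
#'
#' @param line A single pileup line.
#' @return A `ss_pileup` tibble with one row per read observation.
#' @export
parse_pileup_record <- function(line) {
  stopifnot(is.character(line), length(line) == 1L)
  parse_pileup_lines(line)
}

#' Read a 7-column pileup file
#'
#' @param path Path to a plain-text pileup file.
#' @return A `ss_pileup` tibble (see [pileup_tbl()]).
#' @export
read_pileup <- function(path) {
  parse_pileup_lines(readr::read_lines(path))
}

#' Write a pileup object to 7-column text
#'
#' Inverse of [read_pileup()] for the retained fields: round-tripping
#' preserves the multiset of (call, allele, strand, base quality, mapping
#' quality) at every site.
#'
#' @param pileup A `ss_pileup` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  if (isTRUE(attr(pileup, "sparse"))) {
    abort("write_pileup requires a full pileup (this one is sparse).")
  }
  sites <- pileup_sites(pileup)
  reads <- as_tibble(pileup)
  enc <- encode_pileup_reads(reads)
  key_sites <- paste(sites$contig, sites$pos)
  m <- match(key_sites, enc$key)
  bases <- ifelse(is.na(m), "*", enc$bases[m])
  bq <- ifelse(is.na(m), "*", enc$bq[m])
  mq <- ifelse(is.na(m), "*", enc$mq[m])
  lines <- paste(sites$contig, sites$pos, sites$ref, sites$depth,
                 bases, bq, mq, sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

# per-site encoded strings for write_pileup
encode_pileup_reads <- function(reads) {
  if (nrow(reads) == 0L) {
    return(list(key = character(0), bases = character(0),
                bq = character(0), mq = character(0)))
  }
  fwd <- reads$strand == "+"
  chr <- character(nrow(reads))
  chr[reads$call == "ref"] <- ifelse(fwd[reads$call == "ref"], ".", ",")
  chr[reads$call == "gap"] <- "*"
  snv <- reads$call == "snv"
  chr[snv] <- ifelse(fwd[snv], reads$allele[snv], tolower(reads$allele[snv]))
  ins <- reads$call == "ins"
  if (any(ins)) {
    seqs <- sub("^\\+", "", reads$allele[ins])
    chr[ins] <- paste0(ifelse(fwd[ins], ".", ","), "+", nchar(seqs),
                       ifelse(fwd[ins], seqs, tolower(seqs)))
  }
  del <- reads$call == "del"
  if (any(del)) {
    lens <- as.integer(sub("^-", "", reads$allele[del]))
    # the deleted reference bases are not tracked on the read; emit N runs
    chr[del] <- paste0(ifelse(fwd[del], ".", ","), "-", lens,
                       strrep("N", lens))
  }
  bq_chr <- intToUtf8(reads$baseq + 33L, multiple = TRUE)
  mq_chr <- intToUtf8(reads$mapq + 33L, multiple = TRUE)
  key <- paste(reads$contig, reads$pos)
  f <- factor(key, levels = unique(key))
  list(
    key = levels(f),
    bases = vapply(split(chr, f), paste, character(1), collapse = ""),
    bq = vapply(split(bq_chr, f), paste, character(1), collapse = ""),
    mq = vapply(split(mq_chr, f), paste, character(1), collapse = "")
  )
}

# ---------------------------------------------------------------------------
# Minimal VCF 4.2 (8 fixed columns)

#' Read a minimal 8-column VCF
#'
#' Reads the fixed VCF columns into a tibble of variant records. INFO keys
#' `VAF`, `VQ`, `MQ`, `RMF` and `SAMPLE` are lifted into columns when
#' present. Variant type is classified from the alleles (left-anchored
#' convention: shared anchor base for indels).
#'
#' @param path Path to a plain-text VCF.
#' @return Tibble with columns `contig`, `pos`, `id`, `ref`, `alt`, `type`,
#'   `qual`, `filter`, `info`, plus lifted INFO columns.
#' @export
read_vcf <- function(path) {
  hdr <- readr::read_lines(path)
  if (!any(startsWith(hdr, "#CHROM"))) {
    abort("VCF is missing the #CHROM header line.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(tibble(contig = character(0), pos = integer(0), id = character(0),
                  ref = character(0), alt = character(0), type = character(0),
                  qual = numeric(0), filter = character(0), info = character(0),
                  sample_id = character(0), vaf = numeric(0), vq = numeric(0),
                  mq = numeric(0), rmf = numeric(0)))
  }
  pos <- as.integer(fix$POS)
  if (any(is.na(pos) | pos < 1L)) {
    abort("VCF positions must be integers >= 1 (VCF is 1-based).")
  }
  refa <- toupper(fix$REF)
  alta <- toupper(fix$ALT)
  if (any(grepl("[^ACGT]", refa)) || any(grepl("[^ACGT]", alta)) ||
      any(!nzchar(refa)) || any(!nzchar(alta))) {
    abort("malformed VCF allele: alleles must be non-empty over {A,C,G,T}.")
  }
  type <- classify_alleles(refa, alta)
  info <- fix$INFO
  info[is.na(info)] <- "."
  tibble(
    contig = fix$CHROM,
    pos = pos,
    id = ifelse(is.na(fix$ID), ".", fix$ID),
    ref = refa,
    alt = alta,
    type = type,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    filter = ifelse(is.na(fix$FILTER), ".", fix$FILTER),
    info = info,
    sample_id = info_field(info, "SAMPLE"),
    vaf = as.numeric(info_field(info, "VAF")),
    vq = as.numeric(info_field(info, "VQ")),
    mq = as.numeric(info_field(info, "MQ")),
    rmf = as.numeric(info_field(info, "RMF"))
  )
}

info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
         character(1))
}

#' Classify ref/alt allele pairs
#'
#' Left-anchored VCF convention: equal length-1 alleles are SNVs, a longer
#' alt sharing the ref anchor is an insertion, a longer ref a deletion.
#'
#' @param ref,alt Character vectors of alleles.
#' @return Character vector over `"SNV"`, `"INS"`, `"DEL"`.
#' @export
classify_alleles <- function(ref, alt) {
  ok_snv <- nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
  ok_ins <- nchar(alt) > nchar(ref) & nchar(ref) == 1L &
    substr(alt, 1L, 1L) == ref
  ok_del <- nchar(ref) > nchar(alt) & nchar(alt) == 1L &
    substr(ref, 1L, 1L) == alt
  out <- rep(NA_character_, length(ref))
  out[ok_snv] <- "SNV"
  out[ok_ins] <- "INS"
  out[ok_del] <- "DEL"
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    abort(paste0("malformed VCF allele pair: ", ref[bad], " / ", alt[bad]))
  }
  out
}

#' Write variant records as a minimal 8-column VCF
#'
#' @param variants Tibble with at least `contig`, `pos`, `ref`, `alt`.
#'   Optional columns: `id`, `qual`, `filter`, `vaf`, `vq`, `mq`, `rmf`,
#'   `sample_id` (serialized into INFO).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  v <- as_tibble(variants)
  if (any(v$pos < 1L)) abort("VCF positions must be >= 1 (VCF is 1-based).")
  n <- nrow(v)
  get <- function(col, default) {
    if (col %in% names(v)) v[[col]] else rep(default, n)
  }
  fmt_num <- function(x) {
    ifelse(is.na(x), NA_character_, formatC(x, format = "g", digits = 6))
  }
  info_parts <- rbind(
    ifelse(is.na(get("sample_id", NA_character_)), NA,
           paste0("SAMPLE=", get("sample_id", NA_character_))),
    ifelse(is.na(get("vaf", NA_real_)), NA,
           paste0("VAF=", fmt_num(get("vaf", NA_real_)))),
    ifelse(is.na(get("vq", NA_real_)), NA,
           paste0("VQ=", fmt_num(get("vq", NA_real_)))),
    ifelse(is.na(get("mq", NA_real_)), NA,
           paste0("MQ=", fmt_num(get("mq", NA_real_)))),
    ifelse(is.na(get("rmf", NA_real_)), NA,
           paste0("RMF=", fmt_num(get("rmf", NA_real_))))
  )
  info <- apply(info_parts, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) "." else paste(x, collapse = ";")
  })
  if (n == 0L) info <- character(0)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=somaticsieve-", as.character(utils::packageVersion("somaticsieve"))),
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample identifier\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Tumor variant allele fraction\">",
    "##INFO=<ID=VQ,Number=1,Type=Float,Description=\"Phred-like variant quality\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mean mapping quality of alt reads\">",
    "##INFO=<ID=RMF,Number=1,Type=Float,Description=\"Remappability ambiguous-read fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  qual <- get("qual", NA_real_)
  body <- paste(v$contig, v$pos, get("id", "."), toupper(v$ref),
                toupper(v$alt),
                ifelse(is.na(qual), ".", fmt_num(qual)),
                get("filter", "."), info, sep = "\t")
  readr::write_lines(c(header, body), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# BED4 target intervals

#' Read BED4 target intervals
#'
#' BED is 0-based half-open; intervals are returned in that frame with the
#' interval name (gene) attached. A BED interval `chr1 0 10 G1` covers
#' 1-based positions 1..10.
#'
#' @param path Path to a BED4 file.
#' @return Tibble with columns `contig`, `start` (0-based), `end`
#'   (exclusive), `gene`.
#' @export
read_bed_intervals <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("contig", "start", "end", "gene"),
                         col_types = "ciic", progress = FALSE)
  if (any(is.na(bed$start)) || any(is.na(bed$end))) {
    abort("BED coordinates must be integers.")
  }
  if (any(bed$start < 0L)) abort("BED coordinates must be non-negative.")
  if (any(bed$start >= bed$end)) {
    bad <- which(bed$start >= bed$end)[1]
    abort(paste0("BED interval with start >= end at line ", bad, "."))
  }
  bed
}

#' Write BED4 target intervals
#'
#' @param targets Tibble with `contig`, `start` (0-based), `end`, `gene`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_intervals <- function(targets, path) {
  readr::write_tsv(targets[, c("contig", "start", "end", "gene")], path,
                   col_names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Cohort TSV

#' Read a cohort design table
#'
#' @param path Path to a TSV with header columns `sample` and `group`.
#' @return Tibble with columns `sample`, `group`.
#' @export
read_cohort_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("sample", "group") %in% names(tab))) {
    abort("cohort TSV must have header columns 'sample' and 'group'.")
  }
  if (anyDuplicated(tab$sample)) abort("duplicate sample in cohort TSV.")
  tab[, c("sample", "group")]
}

#' Write a cohort design table
#'
#' @param cohort Tibble with columns `sample`, `group`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  readr::write_tsv(cohort[, c("sample", "group")], path)
  invisible(path)
}
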