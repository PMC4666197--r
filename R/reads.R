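#' Error-free CDR3-centered positive-control reads
#'
#' One read per transcript, a substring of the transcript with the CDR3
#' midpoint at the read midpoint (both midpoints taken with floor); windows
#' that would overhang a transcript boundary are shifted inward so the read
#' keeps its length.  Transcripts shorter than the read length yield the
#' whole transcript, flagged in the `short` column.
#'
#' @param transcripts a `tcr_repertoire` (or any data.frame with `id`,
#'   `sequence`, `cdr3_start`, `cdr3_end` columns).
#' @param read_length read length in nt (>= 25; the benchmark defaults are
#'   50, 76 and 101).
#' @return a read data.frame: `read_id`, `sequence`, `source_transcript`,
#'   `short`.
#' @export
centered_reads <- function(transcripts, read_length) {
  stopifnot(read_length >= 25)
  tlen <- nchar(transcripts$sequence)
  mid <- (transcripts$cdr3_start + transcripts$cdr3_end) %/% 2L
  start <- mid - read_length %/% 2L
  start <- pmax(0L, pmin(start, tlen - read_length))
  short <- tlen < read_length
  start[short] <- 0L
  end <- pmin(start + read_length, tlen)
  data.frame(
    read_id = paste0(transcripts$id, "_r"),
    sequence = substr(transcripts$sequence, start + 1L, end),
    source_transcript = transcripts$id,
    short = short,
    stringsAsFactors = FALSE)
}

#' Truncate reads to a target length
#'
#' Replaces each read by its first `target_length` bases; shorter reads are
#' left unchanged (no padding).
#'
#' @param reads read data.frame or character vector.
#' @param target_length length in nt (>= 1).
#' @return same shape as `reads`.
#' @export
truncate_reads <- function(reads, target_length) {
  stopifnot(target_length >= 1)
  if (is.character(reads))
    return(substr(reads, 1L, target_length))
  reads <- as_read_frame(reads)
  reads$sequence <- substr(reads$sequence, 1L, target_length)
  reads
}

# Non-overlapping dinucleotide shuffle (approximate composition-preserving
# shuffle; see the methods vignette).
dinuc_shuffle <- function(x) {
  n <- nchar(x)
  k <- n %/% 2L
  if (k < 2L) return(x)
  pairs <- substring(x, seq(1L, 2L * k, by = 2L), seq(2L, 2L * k, by = 2L))
  tail <- if (n %% 2L) substr(x, n, n) else ""
  paste0(paste(sample(pairs), collapse = ""), tail)
}

#' TCR-free decoy reads (negative-control stand-in)
#'
#' Generates reads guaranteed to contain no productive anchor-to-anchor CDR3,
#' in three modes: `germline` draws windows from unrecombined germline
#' segments at least one read long (V and C; isolated J and D segments are
#' shorter than a read and germline context beyond the exon is not modelled);
#' `shuffled` dinucleotide-shuffles such windows; `chimeric` plants genuine
#' V- and J-gene fragments without a valid recombined junction, including
#' rare pseudo-rearrangements carrying both anchor motifs out of frame - the
#' TCR-like non-TCR sequence that drives false-positive CDR3 calls at low
#' alignment stringency (see the methods vignette for the subtype
#' composition).  Every batch is verified by running the extractor at the
#' loosest grid stringency (8/8) and regenerating any read that yields a
#' productive CDR3 call.
#'
#' @param ref a `germline_reference`.
#' @param n number of reads.
#' @param read_length read length in nt.
#' @param mode "germline", "shuffled" or "chimeric".
#' @param seed optional integer seed.
#' @return a read data.frame.
#' @export
decoy_reads <- function(ref, n, read_length, mode = c("germline", "shuffled",
                                                      "chimeric"),
                        seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  with_seed(seed, {
    seqs <- generate_decoys(ref, n, read_length, mode)
    for (round in 1:20) {
      ann <- suppressWarnings(extract_candidates_productive(seqs, ref))
      if (!length(ann)) break
      if (round == 20)
        stop("decoy verification failed: productive CDR3 calls persist")
      seqs[ann] <- generate_decoys(ref, length(ann), read_length, mode)
    }
    data.frame(read_id = sprintf("%s%06d", substr(mode, 1, 3), seq_len(n)),
               sequence = seqs, source_transcript = NA_character_,
               stringsAsFactors = FALSE)
  })
}

# indices of sequences that yield a productive CDR3 call at 8/8
extract_candidates_productive <- function(seqs, ref) {
  cand <- scan_candidates(seqs, ref, 8, 8, 0, both_strands = TRUE)
  win <- winner_calls(cand)
  if (!nrow(win)) return(integer(0))
  aa <- translate_nt(ifelse(nchar(win$cdr3) %% 3L == 0L, win$cdr3,
                            NA_character_))
  prod <- !is.na(aa) & !grepl("\\*", aa) & substr(aa, 1, 1) == "C" &
    grepl("[FW]$", aa)
  win$read[prod]
}

generate_decoys <- function(ref, n, read_length, mode) {
  seg <- ref$segments
  # windows come from V and C exons only: J and D exons are too short to
  # yield full-length reads in isolation, and unrecombined J loci are not
  # transcribed as mature transcripts in TCR-negative cells
  long <- seg[seg$segment_type %in% c("V", "C") &
                nchar(seg$sequence) >= read_length, , drop = FALSE]
  if (!nrow(long)) stop("no germline V/C segment is as long as one read")
  germline_window <- function(m) {
    i <- sample.int(nrow(long), m, replace = TRUE)
    maxs <- nchar(long$sequence[i]) - read_length
    s <- floor(runif(m, 0, maxs + 1))
    substr(long$sequence[i], s + 1L, s + read_length)
  }
  switch(mode,
    germline = germline_window(n),
    shuffled = vapply(germline_window(n), dinuc_shuffle, character(1),
                      USE.NAMES = FALSE),
    chimeric = replicate(n, chimeric_read(ref, read_length)))
}

# One chimeric decoy: fragments of real V and J sequence embedded in random
# context, without a valid recombined CDR3.  Fragment boundaries are guarded
# (the adjacent base differs from the germline continuation) so a planted
# fragment never chance-extends into a longer germline match than
# constructed.  Subtypes:
#   vt_jt / vi_jt / jt_vt / v_only / j_only - V 3'-region and/or
#     non-anchored J fragments of 12-20 nt; any J content avoids the anchor
#     codon, so these reads present V-like flanks with at most chance-level
#     J-anchor support (and vice versa).
#   pseudo - a pseudo-rearrangement: a short (8-10 nt) V fragment covering
#     the Cys anchor plus a 12-20 nt J fragment covering the [FW]GXG anchor,
#     spaced to force a frameshifted (non-productive) call.  These emulate
#     the TCR-like transcriptome sequences that yield spurious CDR3 calls at
#     low alignment stringency while showing low similarity to the putative
#     flanking V gene.
chimeric_read <- function(ref, read_length) {
  seg <- ref$segments
  chains <- unique(seg$chain)
  ch <- chains[sample.int(length(chains), 1)]
  vs <- seg[seg$segment_type == "V" & seg$chain == ch, , drop = FALSE]
  js <- seg[seg$segment_type == "J" & seg$chain == ch, , drop = FALSE]
  v <- vs[sample.int(nrow(vs), 1), ]
  j <- js[sample.int(nrow(js), 1), ]
  other <- function(b) sample(setdiff(c("A", "C", "G", "T"),
                                      if (nzchar(b)) b else character(0)), 1)
  guard_frag <- function(seq, s, e) {  # 0-based [s, e) with mismatch guards
    prev <- if (s > 0) substr(seq, s, s) else ""
    nxt <- if (e < nchar(seq)) substr(seq, e + 1L, e + 1L) else ""
    list(frag = paste0(other(prev), substr(seq, s + 1L, e), other(nxt)),
         core_offset = 1L)  # planted germline content starts 1 base in
  }
  flen <- function() sample(12:20, 1)
  v_tail_frag <- function() {   # ends at/just after the Cys anchor
    fl <- flen()
    end <- min(nchar(v$sequence), v$anchor_offset + sample(0:3, 1))
    guard_frag(v$sequence, end - fl, end)$frag
  }
  v_internal_frag <- function() {  # entirely 5' of the anchor
    fl <- flen()
    end <- sample(seq(fl, v$anchor_offset - 1L), 1)
    guard_frag(v$sequence, end - fl, end)$frag
  }
  j_tail_frag <- function() {   # strictly 3' of the anchor codon
    avail <- nchar(j$sequence) - (j$anchor_offset + 3L)
    fl <- min(flen(), avail)
    s <- j$anchor_offset + 3L + sample.int(max(1L, avail - fl + 1L), 1) - 1L
    guard_frag(j$sequence, s, s + fl)$frag
  }
  subtype <- sample(c("vt_jt", "vi_jt", "jt_vt", "v_only", "j_only",
                      "pseudo"),
                    1, prob = c(0.22, 0.22, 0.22, 0.11, 0.11, 0.12))
  if (subtype == "pseudo")
    return(pseudo_rearranged_read(v, j, read_length, other))
  parts <- switch(subtype,
    vt_jt = c(v_tail_frag(), random_dna(sample(0:6, 1)), j_tail_frag()),
    vi_jt = c(v_internal_frag(), random_dna(sample(0:6, 1)), j_tail_frag()),
    jt_vt = c(j_tail_frag(), random_dna(sample(0:6, 1)), v_tail_frag()),
    v_only = v_tail_frag(),
    j_only = j_tail_frag())
  core <- paste(parts, collapse = "")
  pad <- read_length - nchar(core)
  if (pad < 0) return(substr(core, 1L, read_length))
  left <- sample(0:pad, 1)
  paste0(random_dna(left), core, random_dna(pad - left))
}

pseudo_rearranged_read <- function(v, j, read_length, other) {
  # anchored V fragment of 8-10 nt: covers [s_v, e_v) with s_v <= anchor
  fl_v <- sample(8:10, 1)
  e_v <- v$anchor_offset + sample(1:3, 1)
  s_v <- e_v - fl_v
  vfrag <- substr(v$sequence, s_v + 1L, e_v)
  # anchored J fragment of 12-20 nt covering the anchor codon
  fl_j <- sample(12:20, 1)
  s_j_min <- max(0L, j$anchor_offset - (fl_j - 3L))
  s_j <- sample(s_j_min:j$anchor_offset, 1)
  e_j <- min(nchar(j$sequence), s_j + fl_j)
  jfrag <- substr(j$sequence, s_j + 1L, e_j)
  gv1 <- other(substr(v$sequence, s_v, s_v))
  gv2 <- other(substr(v$sequence, e_v + 1L, e_v + 1L))
  gj1 <- other(substr(j$sequence, s_j, s_j))
  gj2 <- other(substr(j$sequence, e_j + 1L, e_j + 1L))
  spacer <- sample(2:5, 1)
  # anchor read positions given layout; pad spacer to force a frameshift
  p_v <- 1L + (v$anchor_offset - s_v)
  p_j <- 1L + nchar(vfrag) + 1L + spacer + 1L + (j$anchor_offset - s_j)
  if ((p_j - p_v) %% 3L == 0L) spacer <- spacer + 1L
  core <- paste0(gv1, vfrag, gv2, random_dna(spacer), gj1, jfrag, gj2)
  pad <- read_length - nchar(core)
  if (pad < 0) return(substr(core, 1L, read_length))
  left <- sample(0:pad, 1)
  paste0(random_dna(left), core, random_dna(pad - left))
}

#' Random background transcripts
#'
#' Plain random-sequence transcripts used as the non-TCR background of
#' [simulate_rnaseq()].
#'
#' @param n number of transcripts.
#' @param length_range inclusive range of transcript lengths.
#' @param seed optional integer seed.
#' @return named character vector of sequences.
#' @export
random_transcripts <- function(n, length_range = c(500, 3000), seed = NULL) {
  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    setNames(random_dna_vec(n, lens), sprintf("bg_%05d", seq_len(n)))
  })
}

#' Expression-weighted RNA-seq simulation with known abundance
#'
#' Assigns each transcript a log-normal expression level, rescaled so the TCR
#' transcripts jointly account for `tcr_fraction` of transcripts, then draws
#' `depth` error-free single-end fragments of length `read_length` (sampling
#' transcripts proportional to abundance times length, fragment start
#' uniform).  An optional uniform substitution error rate is available for
#' robustness experiments; the control datasets are error-free.
#'
#' @param tcr_transcripts a `tcr_repertoire` data.frame.
#' @param background_transcripts named character vector or DNAStringSet of
#'   non-TCR transcripts.
#' @param tcr_fraction fraction of transcripts that are TCR (0 < f < 1).
#' @param depth total number of reads.
#' @param read_length read length in nt.
#' @param seed optional integer seed.
#' @param error_rate per-base substitution error rate (default 0).
#' @return an object of class `simulated_dataset`: list with `reads` (read
#'   data.frame), `read_length`, `depth` and `abundance` (transcript_id, tpm,
#'   is_tcr; tpm sums to 1e6).
#' @export
simulate_rnaseq <- function(tcr_transcripts, background_transcripts,
                            tcr_fraction, depth, read_length, seed = NULL,
                            error_rate = 0) {
  stopifnot(tcr_fraction > 0, tcr_fraction < 1, depth >= 1)
  if (inherits(background_transcripts, "DNAStringSet"))
    background_transcripts <- setNames(as.character(background_transcripts),
                                       names(background_transcripts))
  if (!length(background_transcripts)) stop("background transcripts are empty")
  ids <- c(tcr_transcripts$id, names(background_transcripts))
  seqs <- c(tcr_transcripts$sequence, unname(background_transcripts))
  is_tcr <- c(rep(TRUE, nrow(tcr_transcripts)),
              rep(FALSE, length(background_transcripts)))
  with_seed(seed, {
    raw <- rlnorm(length(seqs), meanlog = 0, sdlog = 1)
    frac <- numeric(length(seqs))
    frac[is_tcr] <- raw[is_tcr] / sum(raw[is_tcr]) * tcr_fraction
    frac[!is_tcr] <- raw[!is_tcr] / sum(raw[!is_tcr]) * (1 - tcr_fraction)
    tpm <- frac * 1e6
    lens <- nchar(seqs)
    pick <- sample.int(length(seqs), depth, replace = TRUE,
                       prob = frac * lens)
    start <- floor(runif(depth, 0, pmax(1L, lens[pick] - read_length + 1L)))
    reads <- substr(seqs[pick], start + 1L, start + read_length)
    if (error_rate > 0) reads <- add_substitution_errors(reads, error_rate)
    structure(list(
      reads = data.frame(read_id = sprintf("sim%08d", seq_len(depth)),
                         sequence = reads,
                         source_transcript = ids[pick],
                         stringsAsFactors = FALSE),
      read_length = read_length, depth = depth,
      abundance = data.frame(transcript_id = ids, tpm = tpm, is_tcr = is_tcr,
                             stringsAsFactors = FALSE)),
      class = "simulated_dataset")
  })
}

add_substitution_errors <- function(reads, rate) {
  vapply(reads, function(r) {
    n <- nchar(r)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(r)
    chars <- strsplit(r, "")[[1]]
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("Simulated RNA-seq dataset:", x$depth, "reads of", x$read_length,
      "nt;", sum(x$abundance$is_tcr), "TCR +",
      sum(!x$abundance$is_tcr), "background transcripts\n")
  invisible(x)
}

#' Read and write FASTQ
#'
#' Thin wrappers over Biostrings I/O.  Written records carry the dummy
#' quality "I" at every base (the simulators are error-free by default).
#'
#' @param reads a read data.frame (`read_id`, `sequence` columns) or a
#'   character vector of sequences.
#' @param path file path (".gz" accepted on read).
#' @return [read_fastq()] returns a read data.frame; [write_fastq()] the
#'   path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  reads <- as_read_frame(reads)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(x), sequence = as.character(x),
             source_transcript = NA_character_, stringsAsFactors = FALSE)
}
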