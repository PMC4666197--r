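#' Germline V/(D)/J/C gene segment references
#'
#' A germline reference holds TCR gene segments with CDR3 anchor annotations:
#' for V segments the 0-based position of the conserved cysteine codon (TGT or
#' TGC) near the 3' end, for J segments the position of the conserved
#' phenylalanine/tryptophan codon opening the [FW]-G-X-G motif near the 5'
#' end.  The CDR3 convention used throughout the package is inclusive of both
#' anchor codons.  Coordinates are 0-based, intervals half-open.
#'
#' @param segments data.frame with columns `name`, `chain` ("alpha"/"beta"),
#'   `segment_type` ("V","D","J","C"), `sequence`, `anchor_offset` (integer,
#'   NA for D and C), `frame_offset` (integer).
#' @param provenance free-text description of where the segments came from.
#' @return An object of class `germline_reference`.
#' @export
germline_reference <- function(segments, provenance = "user-supplied") {
  required <- c("name", "chain", "segment_type", "sequence",
                "anchor_offset", "frame_offset")
  missing_cols <- setdiff(required, names(segments))
  if (length(missing_cols))
    stop("segments is missing columns: ", paste(missing_cols, collapse = ", "))
  segments <- segments[required]
  segments$name <- as.character(segments$name)
  segments$chain <- as.character(segments$chain)
  segments$segment_type <- as.character(segments$segment_type)
  segments$sequence <- toupper(as.character(segments$sequence))
  segments$anchor_offset <- as.integer(segments$anchor_offset)
  segments$frame_offset <- as.integer(segments$frame_offset)
  rownames(segments) <- NULL
  ref <- structure(list(segments = segments, provenance = provenance),
                   class = "germline_reference")
  validate_germline(ref)
  ref
}

#' Validate a germline reference
#'
#' Checks the segment-level invariants (non-empty A/C/G/T sequences, V anchor
#' codon encodes Cys, J anchor opens a [FW]-G-X-G motif) and reference-level
#' invariants (per chain at least one V, J and C, plus one D for beta; unique
#' names within chain and segment type).
#'
#' @param ref a `germline_reference`.
#' @return `ref`, invisibly; errors describe the offending segment.
#' @export
validate_germline <- function(ref) {
  seg <- ref$segments
  if (!nrow(seg)) stop("reference contains no segments")
  if (!all(seg$chain %in% CHAINS))
    stop("chain must be one of: ", paste(CHAINS, collapse = ", "))
  if (!all(seg$segment_type %in% c("V", "D", "J", "C")))
    stop("segment_type must be one of V, D, J, C")
  bad <- !grepl("^[ACGT]+$", seg$sequence)
  if (any(bad))
    stop("segment ", seg$name[which(bad)[1]],
         ": sequence is empty or contains non-ACGT characters")
  dup <- duplicated(seg[c("chain", "segment_type", "name")])
  if (any(dup))
    stop("duplicate segment name within (chain, segment_type): ",
         seg$name[which(dup)[1]])
  for (i in which(seg$segment_type %in% c("V", "J"))) {
    a <- seg$anchor_offset[i]
    s <- seg$sequence[i]
    if (is.na(a) || a < 0 || a + 3 > nchar(s))
      stop("segment ", seg$name[i], ": anchor_offset missing or out of range")
    codon <- substr(s, a + 1, a + 3)
    if (seg$segment_type[i] == "V") {
      if (!codon %in% c("TGT", "TGC"))
        stop("segment ", seg$name[i],
             ": V anchor codon ", codon, " does not encode cysteine")
    } else {
      if (a + 12 > nchar(s))
        stop("segment ", seg$name[i], ": no room for [FW]GXG motif")
      motif_aa <- translate_nt(substr(s, a + 1, a + 12))
      if (!grepl("^[FW]G.G$", motif_aa))
        stop("segment ", seg$name[i], ": anchor motif ", motif_aa,
             " does not match [FW]-G-X-G")
    }
  }
  for (ch in unique(seg$chain)) {
    types <- seg$segment_type[seg$chain == ch]
    need <- c("V", "J", "C", if (ch == "beta") "D")
    miss <- setdiff(need, types)
    if (length(miss))
      stop("chain ", ch, " is missing segment type(s): ",
           paste(miss, collapse = ", "))
  }
  invisible(ref)
}

#' Look up segments of a reference
#'
#' @param ref a `germline_reference`.
#' @param chain "alpha", "beta", or NULL for both.
#' @param segment_type one of "V","D","J","C", or NULL for all.
#' @return the matching rows of the segment table.
#' @export
get_segments <- function(ref, chain = NULL, segment_type = NULL) {
  seg <- ref$segments
  if (!is.null(chain)) seg <- seg[seg$chain %in% chain, , drop = FALSE]
  if (!is.null(segment_type))
    seg <- seg[seg$segment_type %in% segment_type, , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' @export
print.germline_reference <- function(x, ...) {
  seg <- x$segments
  cat("Germline TCR reference (", x$provenance, ")\n", sep = "")
  tab <- table(seg$chain, seg$segment_type)
  print(tab)
  invisible(x)
}

#' Load a germline reference from FASTA plus an anchor table
#'
#' The anchor table is a TSV with header
#' `name, chain, segment_type, anchor_offset, frame_offset`; every FASTA
#' record must match exactly one row.  `anchor_offset` may be empty/NA for D
#' and C segments.
#'
#' @param fasta_path path to the segment FASTA.
#' @param anchors_path path to the anchor TSV.
#' @return a validated `germline_reference`.
#' @export
load_germline <- function(fasta_path, anchors_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  anchors <- read.delim(anchors_path, stringsAsFactors = FALSE)
  required <- c("name", "chain", "segment_type", "anchor_offset", "frame_offset")
  missing_cols <- setdiff(required, names(anchors))
  if (length(missing_cols))
    stop("anchor table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  m <- match(names(seqs), anchors$name)
  if (anyNA(m))
    stop("no anchor row for segment(s): ",
         paste(names(seqs)[is.na(m)], collapse = ", "))
  if (anyDuplicated(anchors$name))
    stop("anchor table has duplicated name(s): ",
         anchors$name[anyDuplicated(anchors$name)])
  extra <- setdiff(anchors$name, names(seqs))
  if (length(extra))
    stop("anchor row(s) without FASTA record: ", paste(extra, collapse = ", "))
  anchors <- anchors[m, ]
  segments <- data.frame(
    name = anchors$name, chain = anchors$chain,
    segment_type = anchors$segment_type,
    sequence = as.character(seqs),
    anchor_offset = anchors$anchor_offset,
    frame_offset = anchors$frame_offset,
    stringsAsFactors = FALSE)
  germline_reference(segments,
                     provenance = paste0("loaded from ", fasta_path))
}

#' Write a germline reference to FASTA plus an anchor table
#'
#' Inverse of [load_germline()]: `load_germline()` on the written files
#' reconstructs an equal reference.
#'
#' @param ref a `germline_reference`.
#' @param fasta_path,anchors_path output paths.
#' @return the two paths, invisibly.
#' @export
write_germline <- function(ref, fasta_path, anchors_path) {
  seg <- ref$segments
  seqs <- Biostrings::DNAStringSet(seg$sequence)
  names(seqs) <- seg$name
  Biostrings::writeXStringSet(seqs, fasta_path)
  write.table(seg[c("name", "chain", "segment_type", "anchor_offset",
                    "frame_offset")],
              anchors_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta_path, anchors = anchors_path))
}

sample_codons <- function(n) {
  paste(sample(STOP_FREE_CODONS, n, replace = TRUE), collapse = "")
}

generate_v_segment <- function() {
  n_codons <- sample(90:106, 1)
  len <- 3L * n_codons
  # conserved Cys 15 nt from the 3' end; everything upstream stop-free in
  # frame 0, the 4 codons after the anchor lie inside the CDR3
  paste0(sample_codons(n_codons - 5L),
         sample(c("TGT", "TGC"), 1),
         sample_codons(4L))
}

generate_j_segment <- function() {
  a <- sample(15:21, 1)                       # anchor offset
  t_min <- ceiling((45 - a - 12) / 3)
  t_max <- floor((60 - a - 12) / 3)
  tail_codons <- sample(t_min:t_max, 1)
  motif <- paste0(sample(c("TTT", "TTC", "TGG"), 1),
                  paste0("GG", sample(c("A", "C", "G", "T"), 1)),
                  sample(STOP_FREE_CODONS, 1),
                  paste0("GG", sample(c("A", "C", "G", "T"), 1)))
  # the pre-anchor region encodes the CDR3 tail: stop-free in the anchor
  # frame, as in real J genes (the leading a %% 3 bases sit in the junction)
  prefix <- paste0(random_dna(a %% 3L), sample_codons(a %/% 3L))
  list(sequence = paste0(prefix, motif, sample_codons(tail_codons)),
       anchor_offset = a)
}

pairwise_identity <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0)
  va <- substring(a, seq_len(n), seq_len(n))
  vb <- substring(b, seq_len(n), seq_len(n))
  mean(va == vb)
}

#' Generate a synthetic fixture germline reference
#'
#' Produces segments with realistic geometry: V segments of 270-318 nt with
#' the conserved Cys codon 15 nt from the 3' end, J segments of 45-60 nt with
#' the [FW]GXG anchor 15-24 nt from the 5' end, D segments of 10-16 nt and a
#' C segment of 300 nt.  Segments are mutually distinguishable (pairwise
#' identity below 80% over the regions the extractor aligns) and the result
#' is deterministic given the seed.
#'
#' @param n_v,n_d,n_j segment counts (all >= 1; `n_d` is ignored for alpha).
#' @param chain "alpha", "beta", or both (the default generates one locus per
#'   chain requested).
#' @param seed integer seed.
#' @return a validated `germline_reference`.
#' @export
generate_fixture_germline <- function(n_v = 5, n_d = 2, n_j = 5,
                                      chain = "beta", seed = 1) {
  stopifnot(all(chain %in% CHAINS))
  if (n_v < 1 || n_j < 1) stop("segment counts must be >= 1")
  if ("beta" %in% chain && n_d < 1) stop("beta requires n_d >= 1")
  with_seed(seed, {
    rows <- list()
    for (ch in chain) {
      prefix <- if (ch == "alpha") "TRA" else "TRB"
      # V segments, regenerated until mutually distinguishable over the
      # 3'-most 50 nt (the region short reads can align)
      v_seqs <- character(0)
      while (length(v_seqs) < n_v) {
        cand <- generate_v_segment()
        tails <- substr(c(v_seqs, cand),
                        nchar(c(v_seqs, cand)) - 49,
                        nchar(c(v_seqs, cand)))
        ok <- TRUE
        for (old in head(tails, -1))
          if (pairwise_identity(old, tails[length(tails)]) >= 0.8) ok <- FALSE
        if (ok) v_seqs <- c(v_seqs, cand)
      }
      j_list <- list()
      while (length(j_list) < n_j) {
        cand <- generate_j_segment()
        ok <- TRUE
        for (old in j_list)
          if (pairwise_identity(old$sequence, cand$sequence) >= 0.8) ok <- FALSE
        if (ok) j_list[[length(j_list) + 1]] <- cand
      }
      rows[[length(rows) + 1]] <- data.frame(
        name = sprintf("%sV%d", prefix, seq_len(n_v)),
        chain = ch, segment_type = "V", sequence = v_seqs,
        anchor_offset = nchar(v_seqs) - 15L, frame_offset = 0L,
        stringsAsFactors = FALSE)
      if (ch == "beta") {
        # D genes are translatable in all three reading frames (as the real
        # TRBD genes are); reject draws with a stop in any frame
        d_seqs <- vapply(sample(10:16, n_d, replace = TRUE), function(len) {
          repeat {
            cand <- random_dna(len)
            frames <- vapply(0:2, function(f) {
              n_cod <- (len - f) %/% 3L
              if (n_cod < 1L) return("")
              translate_nt(substr(cand, f + 1L, f + 3L * n_cod))
            }, character(1))
            if (!any(grepl("\\*", frames))) return(cand)
          }
        }, character(1))
        rows[[length(rows) + 1]] <- data.frame(
          name = sprintf("%sD%d", prefix, seq_len(n_d)),
          chain = ch, segment_type = "D", sequence = d_seqs,
          anchor_offset = NA_integer_, frame_offset = 0L,
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        name = sprintf("%sJ%d", prefix, seq_len(n_j)),
        chain = ch, segment_type = "J",
        sequence = vapply(j_list, `[[`, character(1), "sequence"),
        anchor_offset = vapply(j_list, function(x) as.integer(x$anchor_offset),
                               integer(1)),
        frame_offset = vapply(j_list,
                              function(x) as.integer(x$anchor_offset %% 3),
                              integer(1)),
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        name = sprintf("%sC", prefix), chain = ch, segment_type = "C",
        sequence = paste0(sample_codons(30L), random_dna(210L)),
        anchor_offset = NA_integer_, frame_offset = 0L,
        stringsAsFactors = FALSE)
    }
    germline_reference(do.call(rbind, rows),
                       provenance = sprintf("synthetic fixture (seed %d)", seed))
  })
}
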