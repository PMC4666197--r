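#' In silico V(D)J recombination
#'
#' Simulate recombined TCR transcripts from a germline reference: V, (D), J
#' and C segments are chosen uniformly at random, junctions are edited
#' according to a [junction_model()], and the parts are concatenated as
#' trimmed V + insertions + (trimmed D + insertions, beta only) + trimmed J +
#' C.  Trim draws that would consume a whole segment are redrawn (bounded).
#'
#' @param ref a `germline_reference`.
#' @param chain "alpha" or "beta".
#' @param model a `junction_model`.
#' @param seed optional integer seed.
#' @return [recombine()] returns a single `recombined_transcript` (a list
#'   with segment names, the assembled sequence and the junction event);
#'   the internal batch interface underlies [simulate_repertoire()].
#' @export
recombine <- function(ref, chain, model = junction_model(), seed = NULL) {
  row <- with_seed(seed, recombine_batch(ref, chain, model, 1L))
  structure(list(
    chain = chain,
    v_name = row$v_name, d_name = row$d_name, j_name = row$j_name,
    c_name = row$c_name, sequence = row$sequence,
    junction = as.list(row[c("del_v3", "del_d5", "del_d3", "del_j5",
                             "ins_vd", "ins_dj", "ins_vj")]),
    cdr3_nt_interval = NULL, cdr3_nt = NA_character_,
    cdr3_aa = NA_character_, productive = NA),
    class = "recombined_transcript")
}

#' @export
print.recombined_transcript <- function(x, ...) {
  cat("Recombined", x$chain, "transcript:",
      x$v_name, if (!is.na(x$d_name)) x$d_name, x$j_name, x$c_name, "\n")
  cat(nchar(x$sequence), "nt",
      if (isTRUE(x$productive)) "(productive)" else "", "\n")
  invisible(x)
}

recombine_batch <- function(ref, chain, model, n) {
  vs <- get_segments(ref, chain, "V")
  js <- get_segments(ref, chain, "J")
  cs <- get_segments(ref, chain, "C")
  if (!nrow(vs) || !nrow(js) || !nrow(cs))
    stop("reference lacks required segment types for chain ", chain)
  beta <- chain == "beta"
  ds <- if (beta) get_segments(ref, chain, "D") else NULL
  if (beta && !nrow(ds)) stop("beta chain requires D segments")

  vi <- sample.int(nrow(vs), n, replace = TRUE)
  ji <- sample.int(nrow(js), n, replace = TRUE)
  ci <- sample.int(nrow(cs), n, replace = TRUE)
  di <- if (beta) sample.int(nrow(ds), n, replace = TRUE) else rep(NA_integer_, n)

  jn <- sample_junction_batch(model, chain, n)
  v_len <- nchar(vs$sequence[vi])
  j_len <- nchar(js$sequence[ji])
  d_len <- if (beta) nchar(ds$sequence[di]) else rep(NA_integer_, n)
  for (try in 1:100) {
    bad <- jn$del_v3 >= v_len | jn$del_j5 >= j_len
    if (beta) bad <- bad | (jn$del_d5 + jn$del_d3) >= d_len
    if (!any(bad)) break
    if (try == 100)
      stop("could not draw junction trims compatible with segment lengths")
    jn[bad, ] <- sample_junction_batch(model, chain, sum(bad))
  }

  v_part <- substr(vs$sequence[vi], 1L, v_len - jn$del_v3)
  j_part <- substr(js$sequence[ji], jn$del_j5 + 1L, j_len)
  if (beta) {
    d_part <- substr(ds$sequence[di], jn$del_d5 + 1L, d_len - jn$del_d3)
    seqs <- paste0(v_part, jn$ins_vd, d_part, jn$ins_dj, j_part,
                   cs$sequence[ci])
  } else {
    seqs <- paste0(v_part, jn$ins_vj, j_part, cs$sequence[ci])
  }
  cbind(data.frame(chain = chain,
                   v_name = vs$name[vi],
                   d_name = if (beta) ds$name[di] else NA_character_,
                   j_name = js$name[ji],
                   c_name = cs$name[ci],
                   sequence = seqs, stringsAsFactors = FALSE),
        jn)
}

# Shared scanner wrapper: segments sorted by name so the compiled tie-break
# (lowest segment index) is lexicographic.
scan_candidates <- function(sequences, ref, min_v, min_j, max_mismatches,
                            both_strands) {
  seg <- get_segments(ref, segment_type = c("V", "J"))
  seg <- seg[order(seg$name), ]
  cand <- scan_reads_cpp(sequences, seg$sequence,
                         as.integer(seg$chain == "beta"),
                         seg$segment_type == "V",
                         as.integer(seg$anchor_offset),
                         as.integer(min_v), as.integer(min_j),
                         as.integer(max_mismatches), isTRUE(both_strands))
  cand$v_name <- seg$name[cand$v_seg]
  cand$j_name <- seg$name[cand$j_seg]
  cand$chain <- CHAINS[cand$chain + 1L]
  cand
}

# Deterministic per-read winner: longest combined alignment, ties by chain,
# CDR3 sequence, then V and J name.
winner_calls <- function(cand) {
  if (!nrow(cand)) return(cand)
  ord <- order(cand$read, -(cand$v_len + cand$j_len), cand$chain,
               cand$cdr3, cand$v_name, cand$j_name, method = "radix")
  cand <- cand[ord, , drop = FALSE]
  cand[!duplicated(cand$read), , drop = FALSE]
}

#' Annotate the CDR3 of one or more sequences
#'
#' Scans each sequence for the best-matching V segment (ungapped match of at
#' least `min_v_align` nt ending at or 3' of the conserved Cys anchor) and J
#' segment (match of at least `min_j_align` nt covering the [FW]GXG anchor
#' codon).  The CDR3 spans anchor codon to anchor codon, both inclusive.
#'
#' @param sequence character vector of DNA sequences (scanned forward only).
#' @param ref a `germline_reference`.
#' @param min_v_align,min_j_align minimum alignment lengths in nt (default
#'   12, the extractor default; truth annotation of simulated transcripts
#'   uses the stringent 20/20).
#' @param max_mismatches per-alignment mismatch budget (default 0).
#' @return a data.frame with one row per sequence: `v_name`, `j_name`,
#'   `cdr3_start`, `cdr3_end` (0-based half-open into the sequence),
#'   `cdr3_nt`, `cdr3_aa` (NA when out of frame), `in_frame`, `has_stop` and
#'   `productive`.  Rows are all-NA where no CDR3 was found.
#' @export
annotate_cdr3 <- function(sequence, ref, min_v_align = 12, min_j_align = 12,
                          max_mismatches = 0) {
  stopifnot(min_v_align >= 1, min_j_align >= 1)
  out <- data.frame(chain = NA_character_, v_name = NA_character_,
                    j_name = NA_character_, cdr3_start = NA_integer_,
                    cdr3_end = NA_integer_, cdr3_nt = NA_character_,
                    cdr3_aa = NA_character_, in_frame = NA, has_stop = NA,
                    productive = NA,
                    stringsAsFactors = FALSE)[rep(1L, length(sequence)), ]
  rownames(out) <- NULL
  cand <- scan_candidates(sequence, ref, min_v_align, min_j_align,
                          max_mismatches, both_strands = FALSE)
  win <- winner_calls(cand)
  if (!nrow(win)) return(out)
  i <- win$read
  out$chain[i] <- win$chain
  out$v_name[i] <- win$v_name
  out$j_name[i] <- win$j_name
  out$cdr3_start[i] <- win$v_pos
  out$cdr3_end[i] <- win$j_pos + 3L
  out$cdr3_nt[i] <- win$cdr3
  out$in_frame[i] <- nchar(win$cdr3) %% 3L == 0L
  out$cdr3_aa[i] <- translate_nt(ifelse(out$in_frame[i], win$cdr3,
                                        NA_character_))
  out$has_stop[i] <- !is.na(out$cdr3_aa[i]) & grepl("\\*", out$cdr3_aa[i])
  out$productive[i] <- out$in_frame[i] & !out$has_stop[i] &
    !is.na(out$cdr3_aa[i]) &
    substr(out$cdr3_aa[i], 1L, 1L) == "C" &
    grepl("[FW]$", out$cdr3_aa[i])
  out
}

#' Simulate a productive TCR repertoire
#'
#' Rejection-samples [recombine()] draws, keeping transcripts whose CDR3 is
#' annotatable at stringent truth settings (minimum V and J alignment 20 nt),
#' in frame, stop-free from the V reading frame through the C segment start,
#' and bounded by the conserved Cys and Phe/Trp anchors.
#'
#' @param ref a `germline_reference`.
#' @param chain "alpha" or "beta".
#' @param n_target number of productive transcripts to return.
#' @param model a `junction_model`.
#' @param seed optional integer seed.
#' @param min_v_align,min_j_align truth-annotation stringency (default 20/20).
#' @param max_attempts rejection-sampling bound (default 10000 * n_target).
#' @return a data.frame of class `tcr_repertoire`: one row per productive
#'   transcript with segment names, sequence, junction fields, the truth CDR3
#'   interval (0-based half-open), `cdr3_nt`, `cdr3_aa` and `productive`.
#' @export
simulate_repertoire <- function(ref, chain, n_target,
                                model = junction_model(), seed = NULL,
                                min_v_align = 20, min_j_align = 20,
                                max_attempts = 10000 * n_target) {
  stopifnot(n_target >= 1)
  with_seed(seed, {
    kept <- list()
    n_kept <- 0L
    attempts <- 0L
    batch <- max(200L, ceiling(n_target * 1.25))
    while (n_kept < n_target) {
      if (attempts >= max_attempts)
        stop("rejection sampling exceeded ", max_attempts, " attempts")
      b <- recombine_batch(ref, chain, model, batch)
      ann <- annotate_cdr3(b$sequence, ref, min_v_align, min_j_align)
      ok <- !is.na(ann$productive) & ann$productive &
        full_orf_stop_free(b$sequence, ann$cdr3_end, ref, chain)
      attempts <- attempts + batch
      if (any(ok)) {
        keep <- cbind(b[ok, , drop = FALSE], ann[ok, c(
          "cdr3_start", "cdr3_end", "cdr3_nt", "cdr3_aa"), drop = FALSE])
        kept[[length(kept) + 1L]] <- keep
        n_kept <- n_kept + sum(ok)
      }
      if (attempts >= 1000L && n_kept / attempts < 0.01)
        stop("acceptance rate below 1%; check the reference and junction model")
    }
    out <- do.call(rbind, kept)[seq_len(n_target), , drop = FALSE]
    out$productive <- TRUE
    out$id <- sprintf("%s_%06d", chain, seq_len(n_target))
    rownames(out) <- NULL
    out <- out[c("id", setdiff(names(out), "id"))]
    class(out) <- c("tcr_repertoire", "data.frame")
    attr(out, "chain") <- chain
    out
  })
}

# No stop codon from the V reading frame through the C segment start.
full_orf_stop_free <- function(sequences, cdr3_end, ref, chain) {
  cs <- get_segments(ref, chain, "C")
  c_len <- setNames(nchar(cs$sequence), cs$name)
  # all fixture/validated V segments use frame offset 0; the variable region
  # runs to the start of C
  var_len <- nchar(sequences) - min(c_len)
  n <- length(sequences)
  ok <- rep(FALSE, n)
  idx <- which(!is.na(cdr3_end))
  if (!length(idx)) return(ok)
  region <- substr(sequences[idx], 1L, 3L * (var_len[idx] %/% 3L))
  aa <- translate_nt(region)
  ok[idx] <- !grepl("\\*", aa)
  ok
}
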