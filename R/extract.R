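#' Extraction parameters
#'
#' Tunable stringency of the CDR3 caller: minimum ungapped alignment lengths
#' for the V and J flanks (defaults 12/12, the caller's default stringency;
#' 20/20 is the stringent setting used for truth annotation), a per-alignment
#' mismatch budget (default 0; error-free control reads need none) and
#' whether to scan both strands (default TRUE; bulk RNA-seq libraries of the
#' relevant era are unstranded).
#'
#' @param min_v_align,min_j_align minimum alignment lengths in nt (>= 1).
#' @param max_mismatches mismatch budget per alignment (>= 0; N counts as a
#'   mismatch).
#' @param both_strands scan the reverse complement as well.
#' @return an object of class `extraction_params`.
#' @export
extraction_params <- function(min_v_align = 12, min_j_align = 12,
                              max_mismatches = 0, both_strands = TRUE) {
  stopifnot(min_v_align >= 1, min_j_align >= 1, max_mismatches >= 0)
  structure(list(min_v_align = as.integer(min_v_align),
                 min_j_align = as.integer(min_j_align),
                 max_mismatches = as.integer(max_mismatches),
                 both_strands = isTRUE(both_strands)),
            class = "extraction_params")
}

#' Clean reads before extraction
#'
#' Keeps reads strictly longer than 40 nt whose bases are all standard
#' (A, C, G, T or N).
#'
#' @param reads read data.frame or character vector.
#' @return the retained reads, same shape as the input.
#' @export
clean_reads <- function(reads) {
  seqs <- if (is.character(reads)) reads else as_read_frame(reads)$sequence
  keep <- nchar(seqs) > 40L & grepl("^[ACGTN]+$", seqs)
  if (is.character(reads)) reads[keep]
  else {
    out <- as_read_frame(reads)[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
}

#' Subsample reads without replacement
#'
#' Uniform, seeded subsample; requesting more reads than available is an
#' error tagged "insufficient depth" (mirroring the removal of samples too
#' shallow for depth normalization).
#'
#' @param reads read data.frame or character vector.
#' @param n sample size.
#' @param seed optional integer seed.
#' @return the sampled reads, same shape as the input.
#' @export
subsample_reads <- function(reads, n, seed = NULL) {
  size <- if (is.character(reads)) length(reads) else nrow(as_read_frame(reads))
  if (n > size)
    stop("insufficient depth: requested ", n, " reads from ", size)
  with_seed(seed, {
    idx <- sort(sample.int(size, n))
    if (is.character(reads)) reads[idx]
    else {
      out <- as_read_frame(reads)[idx, , drop = FALSE]
      rownames(out) <- NULL
      out
    }
  })
}

#' Extract CDR3 clonotypes from reads
#'
#' Per read (and its reverse complement when `both_strands`), finds the V
#' segment with the longest ungapped match ending at or 3' of its Cys anchor
#' and the J segment with the longest ungapped match covering its [FW]GXG
#' anchor codon; a call requires both match lengths to reach the configured
#' minima, both anchor positions inside the read, and the V anchor strictly
#' upstream of the J anchor.  The CDR3 spans anchor codon to anchor codon
#' inclusive.  Calls are aggregated by (chain, CDR3 nt, V, J).  Out-of-frame
#' and stop-containing calls are retained but flagged; remove them with
#' [filter_clonotypes()].
#'
#' @param reads read data.frame or character vector (pass through
#'   [clean_reads()] first for real data).
#' @param ref a `germline_reference`.
#' @param params an [extraction_params()] object.
#' @return a data.frame of class `clonotype_table`, ordered by (chain,
#'   read_count decreasing, cdr3_nt), with columns `chain`, `cdr3_nt`,
#'   `cdr3_aa` (NA when out of frame), `v_name`, `j_name`, `read_count`,
#'   `frameshift`, `has_stop`.
#' @export
extract_cdr3 <- function(reads, ref, params = extraction_params()) {
  reads <- as_read_frame(reads)
  validate_germline(ref)
  cand <- scan_candidates(reads$sequence, ref, params$min_v_align,
                          params$min_j_align, params$max_mismatches,
                          params$both_strands)
  calls <- winner_calls(cand)
  clonotype_table_from_calls(calls, params, n_reads = nrow(reads))
}

clonotype_table_from_calls <- function(calls, params, n_reads) {
  if (!nrow(calls)) {
    out <- data.frame(chain = character(0), cdr3_nt = character(0),
                      cdr3_aa = character(0), v_name = character(0),
                      j_name = character(0), read_count = integer(0),
                      frameshift = logical(0), has_stop = logical(0),
                      stringsAsFactors = FALSE)
  } else {
    key <- paste(calls$chain, calls$cdr3, calls$v_name, calls$j_name,
                 sep = "\r")
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    parts <- strsplit(agg$key, "\r", fixed = TRUE)
    out <- data.frame(
      chain = vapply(parts, `[`, character(1), 1L),
      cdr3_nt = vapply(parts, `[`, character(1), 2L),
      v_name = vapply(parts, `[`, character(1), 3L),
      j_name = vapply(parts, `[`, character(1), 4L),
      read_count = as.integer(agg$Freq),
      stringsAsFactors = FALSE)
    out$frameshift <- nchar(out$cdr3_nt) %% 3L != 0L
    out$cdr3_aa <- translate_nt(ifelse(out$frameshift, NA_character_,
                                       out$cdr3_nt))
    out$has_stop <- !is.na(out$cdr3_aa) & grepl("\\*", out$cdr3_aa)
    out <- out[order(out$chain, -out$read_count, out$cdr3_nt), ]
    out <- out[c("chain", "cdr3_nt", "cdr3_aa", "v_name", "j_name",
                 "read_count", "frameshift", "has_stop")]
    rownames(out) <- NULL
  }
  structure(out, class = c("clonotype_table", "data.frame"),
            params = params, n_input_reads = n_reads)
}

#' @export
print.clonotype_table <- function(x, ...) {
  p <- attr(x, "params")
  cat("Clonotype table:", nrow(x), "clonotypes,",
      sum(x$read_count), "reads assigned")
  if (!is.null(p)) cat(" (minV =", p$min_v_align, ", minJ =",
                       p$min_j_align, ")")
  cat("\n")
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Remove out-of-frame and stop-containing clonotypes
#'
#' Drops clonotypes whose CDR3 nt length is not a multiple of three or whose
#' amino-acid sequence contains a stop.
#'
#' @param table a `clonotype_table`.
#' @return the filtered `clonotype_table`.
#' @export
filter_clonotypes <- function(table) {
  keep <- !table$frameshift & !table$has_stop
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(table), params = attr(table, "params"),
            n_input_reads = attr(table, "n_input_reads"))
}

#' Collapse a clonotype table to amino-acid level
#'
#' Sums read counts over nucleotide variants per (chain, CDR3 aa) and counts
#' the distinct nucleotide sequences per amino-acid sequence (convergent
#' recombination).  Requires a filtered (productive-only) table.
#'
#' @param table a filtered `clonotype_table`.
#' @return data.frame with `chain`, `cdr3_aa`, `read_count`,
#'   `n_nt_variants`.
#' @export
collapse_to_aa <- function(table) {
  if (any(table$frameshift | table$has_stop))
    stop("collapse_to_aa expects a filtered clonotype table")
  if (!nrow(table))
    return(data.frame(chain = character(0), cdr3_aa = character(0),
                      read_count = integer(0), n_nt_variants = integer(0)))
  key <- paste(table$chain, table$cdr3_aa, sep = "\r")
  counts <- tapply(table$read_count, key, sum)
  variants <- tapply(table$cdr3_nt, key, function(x) length(unique(x)))
  parts <- strsplit(names(counts), "\r", fixed = TRUE)
  out <- data.frame(chain = vapply(parts, `[`, character(1), 1L),
                    cdr3_aa = vapply(parts, `[`, character(1), 2L),
                    read_count = as.integer(counts),
                    n_nt_variants = as.integer(variants),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, -out$read_count, out$cdr3_aa), ]
  rownames(out) <- NULL
  out
}

#' Write a clonotype table with a provenance sidecar
#'
#' TSV with header `chain, cdr3_nt, cdr3_aa, v_name, j_name, read_count`
#' plus a JSON sidecar (`<path>.json`) recording the extraction parameters
#' and input read count.
#'
#' @param table a `clonotype_table`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_clonotypes <- function(table, path) {
  write.table(as.data.frame(table)[c("chain", "cdr3_nt", "cdr3_aa",
                                     "v_name", "j_name", "read_count")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  p <- attr(table, "params")
  jsonlite::write_json(
    list(params = p[c("min_v_align", "min_j_align", "max_mismatches",
                      "both_strands")],
         n_input_reads = attr(table, "n_input_reads"),
         n_clonotypes = nrow(table)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
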