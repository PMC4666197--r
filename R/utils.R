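# Internal helpers shared across modules.

CHAINS <- c("alpha", "beta")

STOP_FREE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
})

# Evaluate expr under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_dna_vec <- function(count, lengths) {
  lengths <- rep_len(lengths, count)
  vapply(lengths, random_dna, character(1))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Translate in-frame nucleotide strings; fuzzy codons (N) become X.
translate_nt <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & nchar(x) %% 3L == 0L & nchar(x) > 0L
  if (any(ok)) {
    out[ok] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(x[ok]),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  out
}

# Normalize read input (character vector or data.frame with a sequence
# column) to a read data.frame.
as_read_frame <- function(reads) {
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
    return(data.frame(read_id = ids, sequence = unname(reads),
                      source_transcript = NA_character_,
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(reads), "sequence" %in% names(reads))
  if (!"read_id" %in% names(reads))
    reads$read_id <- sprintf("read%06d", seq_len(nrow(reads)))
  if (!"source_transcript" %in% names(reads))
    reads$source_transcript <- NA_character_
  rownames(reads) <- NULL
  reads
}

`%||%` <- function(a, b) if (is.null(a)) b else a
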