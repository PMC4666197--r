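test_that("centered reads place the CDR3 midpoint at the read midpoint with floor ties", {
  tx <- data.frame(id = "t1",
                   sequence = paste(rep("ACGT", 50), collapse = ""),
                   cdr3_start = 100L, cdr3_end = 145L,
                   stringsAsFactors = FALSE)
  r <- centered_reads(tx, 50)
  # midpoint floor((100+145)/2) = 122; window [97, 147)
  expect_identical(r$sequence, substr(tx$sequence, 98, 147))
  expect_false(r$short)
})

test_that("reads clip to the transcript and keep their length by shifting inward", {
  tx <- data.frame(id = "t1", sequence = cdr3tools:::with_seed(1, cdr3tools:::random_dna(80)),
                   cdr3_start = 2L, cdr3_end = 47L, stringsAsFactors = FALSE)
  r <- centered_reads(tx, 50)
  expect_equal(nchar(r$sequence), 50)
  expect_identical(r$sequence, substr(tx$sequence, 1, 50))  # shifted to the start
  # transcript shorter than the read: whole transcript, flagged
  short_tx <- data.frame(id = "t2", sequence = substr(tx$sequence, 1, 40),
                         cdr3_start = 2L, cdr3_end = 32L, stringsAsFactors = FALSE)
  r2 <- centered_reads(short_tx, 50)
  expect_true(r2$short)
  expect_identical(r2$sequence, short_tx$sequence)
})

test_that("centered reads long enough to hold the CDR3 always contain it", {
  rep_b <- fix_repertoire("beta")
  for (L in c(76, 101)) {
    r <- centered_reads(rep_b, L)
    fits <- nchar(rep_b$cdr3_nt) + 6 <= L
    expect_true(all(mapply(grepl, rep_b$cdr3_nt[fits], r$sequence[fits],
                           MoreArgs = list(fixed = TRUE))))
  }
})

test_that("truncation takes prefixes, never pads, and composes", {
  reads <- c(a = paste(rep("ACGT", 26), collapse = ""),  # 104 nt
             b = "ACGTACGTAC")
  t50 <- truncate_reads(reads, 50)
  expect_equal(unname(nchar(t50)), c(50, 10))
  expect_identical(unname(substr(reads[1], 1, 50)), unname(t50[1]))
  expect_identical(t50[["b"]], reads[["b"]])  # shorter read unchanged
  chained <- truncate_reads(truncate_reads(truncate_reads(reads, 101), 76), 50)
  expect_identical(chained, t50)
})

test_that("decoy generation is deterministic and mode-tagged", {
  ref <- fix_ref()
  a <- decoy_reads(ref, 500, 50, "germline", seed = 9)
  b <- decoy_reads(ref, 500, 50, "germline", seed = 9)
  expect_identical(a, b)
  expect_equal(nrow(a), 500)
  expect_true(all(nchar(a$sequence) == 50))
})

test_that("germline decoys never yield CDR3 calls at default stringency", {
  ref <- fix_ref()
  dec <- decoy_reads(ref, 1000, 50, "germline", seed = 10)
  tab <- extract_cdr3(dec, ref, extraction_params(12, 12))
  expect_equal(nrow(tab), 0L)
})

test_that("chimeric decoys carry real V and J fragments but no productive CDR3", {
  ref <- fix_ref()
  dec <- decoy_reads(ref, 4000, 50, "chimeric", seed = 11)
  # spurious, non-productive calls do appear at the loosest stringency...
  tab8 <- extract_cdr3(dec, ref, extraction_params(8, 8))
  expect_gt(nrow(tab8), 0)
  # ...but none survives the productivity filter, by construction
  expect_equal(nrow(filter_clonotypes(tab8)[
    substr(filter_clonotypes(tab8)$cdr3_aa, 1, 1) == "C" &
      grepl("[FW]$", filter_clonotypes(tab8)$cdr3_aa), ]), 0L)
  # many reads carry >= 12 nt of exact V sequence AND >= 12 nt of exact J
  # sequence (oracle: shared 12-mer with some segment)
  segs <- get_segments(ref, segment_type = c("V", "J"))
  both <- vapply(dec$sequence[1:200], function(r) {
    v_hit <- any(vapply(segs$sequence[segs$segment_type == "V"],
                        function(s) shares_kmer_oracle(r, s, 12), logical(1)))
    j_hit <- any(vapply(segs$sequence[segs$segment_type == "J"],
                        function(s) shares_kmer_oracle(r, s, 12), logical(1)))
    v_hit && j_hit
  }, logical(1), USE.NAMES = FALSE)
  expect_gt(mean(both), 0.3)
})

test_that("shuffled decoys keep dinucleotide content but lose segment identity", {
  ref <- fix_ref()
  dec <- decoy_reads(ref, 500, 50, "shuffled", seed = 12)
  tab <- extract_cdr3(dec, ref, extraction_params(12, 12))
  expect_equal(nrow(tab), 0L)
})

test_that("expression-weighted simulation has calibrated abundance and depth", {
  rep_b <- fix_repertoire("beta")
  one_tcr <- rep_b[1, ]
  bg <- setNames(cdr3tools:::with_seed(3, cdr3tools:::random_dna(nchar(one_tcr$sequence))), "bg1")
  ds <- simulate_rnaseq(one_tcr, bg, tcr_fraction = 0.5, depth = 10000,
                        read_length = 50, seed = 13)
  expect_equal(sum(ds$abundance$tpm), 1e6, tolerance = 1e-6)
  expect_equal(nrow(ds$reads), 10000)
  n_tcr_reads <- sum(ds$reads$source_transcript == one_tcr$id)
  expect_true(abs(n_tcr_reads - 5000) < 150)  # binomial 99% interval
})

test_that("vanishing TCR abundance yields no extractable CDR3", {
  # at depth 1e4 and fraction 1e-5 the expected TCR read count is ~0.1
  rep_b <- fix_repertoire("beta")
  bg <- random_transcripts(50, c(500, 1500), seed = 14)
  ds <- simulate_rnaseq(rep_b[1:10, ], bg, tcr_fraction = 1e-5, depth = 1e4,
                        read_length = 50, seed = 15)
  expect_equal(sum(ds$reads$source_transcript %in% rep_b$id), 0)
  tab <- extract_cdr3(clean_reads(ds$reads), fix_ref(), extraction_params())
  expect_equal(sum(tab$cdr3_nt %in% rep_b$cdr3_nt), 0)
})

test_that("FASTQ output round-trips through Biostrings", {
  reads <- data.frame(read_id = c("r1", "r2"),
                      sequence = c("ACGTACGTTGCA", "GGGTTTAAACCC"),
                      source_transcript = NA_character_)
  path <- tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_identical(back$read_id, reads$read_id)
  expect_identical(back$sequence, reads$sequence)
})
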