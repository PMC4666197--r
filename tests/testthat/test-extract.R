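test_that("read cleaning applies the length and alphabet rules strictly", {
  reads <- c(a = paste(rep("A", 40), collapse = ""),             # length 40: dropped
             b = paste(rep("ACGT", 11), collapse = ""),          # 44 nt: kept
             c = paste0(paste(rep("ACGT", 11), collapse = ""), "R"),  # non-standard
             d = paste(rep("N", 50), collapse = ""))             # all N: kept
  kept <- clean_reads(reads)
  expect_identical(names(kept), c("b", "d"))
  exactly41 <- paste(rep("C", 41), collapse = "")
  expect_length(clean_reads(exactly41), 1L)
})

test_that("subsampling is uniform, seeded and errors on insufficient depth", {
  reads <- sprintf("READ%03d", 1:100)
  names(reads) <- reads
  expect_identical(subsample_reads(reads, 100, seed = 1), reads)
  s1 <- subsample_reads(reads, 10, seed = 2)
  s2 <- subsample_reads(reads, 10, seed = 2)
  s3 <- subsample_reads(reads, 10, seed = 3)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_error(subsample_reads(reads, 101), "insufficient depth")
  # inclusion frequency ~ n/N
  hits <- integer(100)
  for (k in 1:500) {
    idx <- match(subsample_reads(reads, 10, seed = 100 + k), reads)
    hits[idx] <- hits[idx] + 1L
  }
  p <- hits / 500
  sigma <- sqrt(0.1 * 0.9 / 500)
  expect_true(all(abs(p - 0.1) < 3.5 * sigma + 1e-9))
})

test_that("planted-read oracle: error-free 101-nt centered reads are recovered exactly", {
  ref <- fix_ref()
  for (seed in c(501, 502, 503, 504, 505)) {
    reps <- simulate_repertoire(ref, if (seed %% 2) "beta" else "alpha",
                                120, seed = seed)
    reads <- centered_reads(reps, 101)
    tab <- extract_cdr3(reads, ref, extraction_params(12, 12))
    # flank sufficiency holds for every 101-nt centered read whose CDR3 fits
    fits <- nchar(reps$cdr3_nt) <= 101 - 24
    expect_true(all(reps$cdr3_nt[fits] %in% tab$cdr3_nt))
    # and every call on these positives is a truth sequence
    expect_true(all(tab$cdr3_nt %in% reps$cdr3_nt))
    # V/J assignments match the truth for unique truth sequences
    m <- match(reps$cdr3_nt, tab$cdr3_nt)
    ok <- !is.na(m) & !duplicated(reps$cdr3_nt)
    expect_true(all(tab$v_name[m[ok]] == reps$v_name[ok]))
    expect_true(all(tab$j_name[m[ok]] == reps$j_name[ok]))
  }
})

test_that("CDR3s longer than the read are never recovered", {
  rep_b <- cached("rep_beta_1000",
                  simulate_repertoire(fix_ref(), "beta", 1000, seed = 405))
  reads <- centered_reads(rep_b, 50)
  tab <- extract_cdr3(reads, fix_ref(), extraction_params(8, 8))
  long <- nchar(rep_b$cdr3_nt) > 50
  expect_gt(sum(long), 0)
  expect_false(any(rep_b$cdr3_nt[long] %in% tab$cdr3_nt))
})

test_that("raising either minimum alignment never adds a clonotype", {
  ref <- fix_ref()
  rep_b <- fix_repertoire("beta")
  cols <- c("read_id", "sequence", "source_transcript")
  reads <- rbind(centered_reads(rep_b, 50)[cols],
                 decoy_reads(ref, 2000, 50, "chimeric", seed = 21)[cols])
  key <- function(tab) paste(tab$chain, tab$cdr3_nt, tab$v_name, tab$j_name)
  loose <- extract_cdr3(reads, ref, extraction_params(8, 8))
  for (p in list(c(12, 8), c(8, 12), c(14, 14), c(26, 26))) {
    tight <- extract_cdr3(reads, ref, extraction_params(p[1], p[2]))
    expect_true(all(key(tight) %in% key(loose)))
  }
})

test_that("clonotype tables are strand symmetric under both_strands", {
  ref <- fix_ref()
  rep_a <- fix_repertoire("alpha")
  reads <- centered_reads(rep_a, 76)
  rc <- reads
  rc$sequence <- cdr3tools:::revcomp(rc$sequence)
  t1 <- extract_cdr3(reads, ref, extraction_params(12, 12))
  t2 <- extract_cdr3(rc, ref, extraction_params(12, 12))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("the stop/frameshift filter removes exactly the flagged clonotypes", {
  tab <- structure(data.frame(
    chain = "beta",
    cdr3_nt = c(paste(rep("TGC", 15), collapse = ""),
                paste(rep("ACGT", 11), collapse = ""),   # 44 nt frameshift
                paste0("TGT", "TGA", "TTT")),            # internal stop
    v_name = "TRBV1", j_name = "TRBJ1", read_count = c(3L, 2L, 1L),
    stringsAsFactors = FALSE), class = c("clonotype_table", "data.frame"))
  tab$frameshift <- nchar(tab$cdr3_nt) %% 3 != 0
  tab$cdr3_aa <- cdr3tools:::translate_nt(ifelse(tab$frameshift, NA, tab$cdr3_nt))
  tab$has_stop <- !is.na(tab$cdr3_aa) & grepl("\\*", tab$cdr3_aa)
  kept <- filter_clonotypes(tab)
  expect_equal(nrow(kept), 1L)
  expect_false(any(kept$frameshift | kept$has_stop))
  expect_identical(as.data.frame(filter_clonotypes(kept)),
                   as.data.frame(kept))  # all-productive table unchanged
})

test_that("amino-acid collapse sums reads and counts convergent nt variants", {
  tab <- structure(data.frame(
    chain = "beta",
    cdr3_nt = c("TGTGCAAGCTTT", "TGCGCAAGCTTT", "TGTAGGAGGTGG"),
    v_name = "TRBV1", j_name = "TRBJ1",
    read_count = c(3L, 5L, 2L), frameshift = FALSE,
    stringsAsFactors = FALSE), class = c("clonotype_table", "data.frame"))
  tab$cdr3_aa <- cdr3tools:::translate_nt(tab$cdr3_nt)
  tab$has_stop <- FALSE
  col <- collapse_to_aa(tab)
  expect_equal(nrow(col), 2L)
  casf <- col[col$cdr3_aa == "CASF", ]
  expect_equal(casf$read_count, 8L)
  expect_equal(casf$n_nt_variants, 2L)
  expect_equal(col$read_count[col$n_nt_variants == 1], 2L)
  expect_equal(sum(col$read_count), sum(tab$read_count))  # conservation
})

test_that("clonotype tables serialize with a provenance sidecar", {
  ref <- fix_ref()
  reads <- centered_reads(fix_repertoire("beta")[1:40, ], 101)
  tab <- extract_cdr3(reads, ref, extraction_params(12, 12))
  path <- tempfile(fileext = ".tsv")
  write_clonotypes(tab, path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(tab))
  expect_identical(back$cdr3_nt, tab$cdr3_nt)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$params$min_v_align, 12)
  expect_equal(side$n_input_reads, 40)
})
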