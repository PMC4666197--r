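# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fix_ref <- function() cached("ref", {
  generate_fixture_germline(5, 2, 5, chain = c("alpha", "beta"), seed = 401)
})

fix_repertoire <- function(chain, n = 300) cached(paste0("rep_", chain, "_", n), {
  simulate_repertoire(fix_ref(), chain, n, seed = 402 + match(chain, c("alpha", "beta")))
})

# tiny hand-built reference: 1 V (anchor TGT), 1 D, 1 J (TTTGGCGCAGGC = FGAG),
# 1 C per requested chain
tiny_segments <- function(chain = "beta") {
  v_seq <- paste0(paste(rep("ACAGTC", 8), collapse = ""), "TGT",
                  "GCAGAAGCTGAA")  # anchor 48, 15 nt from 3' end
  j_seq <- paste0("CAGTA", "TTTGGCGCAGGC", "ACTGAGCTGACCGTGCTG")  # anchor 5
  rows <- list()
  for (ch in chain) {
    p <- if (ch == "alpha") "TRA" else "TRB"
    rows[[length(rows) + 1]] <- data.frame(
      name = c(paste0(p, "V1"), paste0(p, "J1"), paste0(p, "C"),
               if (ch == "beta") paste0(p, "D1")),
      chain = ch,
      segment_type = c("V", "J", "C", if (ch == "beta") "D"),
      sequence = c(v_seq, j_seq, paste(rep("GATTACAGGA", 30), collapse = ""),
                   if (ch == "beta") "GGGACAGGGGGC"),
      anchor_offset = c(48L, 5L, NA, if (ch == "beta") NA),
      frame_offset = c(0L, 2L, 0L, if (ch == "beta") 0L),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# oracle: do two sequences share any exact k-mer?
shares_kmer_oracle <- function(a, b, k) {
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  ka <- substring(a, seq_len(nchar(a) - k + 1L), k:nchar(a))
  kb <- substring(b, seq_len(nchar(b) - k + 1L), k:nchar(b))
  any(ka %in% kb)
}

# oracle: ungapped identity of the 3'-terminal `n` nt of two sequences
tail_identity_oracle <- function(a, b, n = 50) {
  ta <- substr(a, nchar(a) - n + 1, nchar(a))
  tb <- substr(b, nchar(b) - n + 1, nchar(b))
  va <- strsplit(ta, "")[[1]]
  vb <- strsplit(tb, "")[[1]]
  mean(va == vb)
}

# 200 permutation p values from cohorts with no true alpha-beta association
# (shared across the analytics and acceptance suites)
null_calibration_pvals <- function() cached("null_calibration_pvals", {
  pools <- cdr3tools:::with_seed(900, list(alpha = random_aa(80),
                                           beta = random_aa(80)))
  vapply(1:200, function(k) {
    cohort <- cdr3tools:::with_seed(900 + k, {
      do.call(rbind, lapply(sprintf("p%d", 1:6), function(id) {
        data.frame(individual_id = id,
                   chain = rep(c("alpha", "beta"), each = 18),
                   cdr3_aa = c(sample(pools$alpha, 18, replace = TRUE),
                               sample(pools$beta, 18, replace = TRUE)),
                   read_count = 1L, stringsAsFactors = FALSE)
      }))
    })
    pair_cooccurrence_test(cohort, n_iterations = 100,
                           seed = 4000 + k)$p_value
  }, numeric(1))
})

# the desk-scale operating-point benchmark: >= 1000 productive transcripts
# per chain, 50-nt centered error-free positives, 1e5 decoy reads
operating_point_benchmark <- function() cached("operating_point", {
  ref <- generate_fixture_germline(5, 2, 5, chain = c("alpha", "beta"),
                                   seed = 1101)
  reps <- list(alpha = simulate_repertoire(ref, "alpha", 1200, seed = 1102),
               beta = simulate_repertoire(ref, "beta", 1200, seed = 1103))
  negative <- rbind(decoy_reads(ref, 40000, 50, "germline", seed = 1104),
                    decoy_reads(ref, 30000, 50, "shuffled", seed = 1105),
                    decoy_reads(ref, 30000, 50, "chimeric", seed = 1106))
  grids <- list(); selections <- list()
  for (ch in c("alpha", "beta")) {
    pos <- centered_reads(reps[[ch]], 50)
    grids[[ch]] <- grid_search(pos, reps[[ch]], negative, ref, chain = ch)
    selections[[ch]] <- select_optimal(grids[[ch]], 0)
  }
  list(ref = ref, repertoires = reps, negative = negative,
       grids = grids, selections = selections)
})

random_aa <- function(n, len_range = c(8, 18)) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aas, sample(len_range[1]:len_range[2], 1), replace = TRUE),
          collapse = "")
  }, character(1))
}
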