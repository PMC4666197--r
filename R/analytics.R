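# Repertoire-level statistics on amino-acid clonotypes.
#
# The common input is a long-format cohort data.frame with columns
# individual_id, tissue ("tumor"/"normal"; optional where irrelevant),
# chain ("alpha"/"beta"), cdr3_aa and read_count (cdr3_nt optional, used for
# convergent-recombination counts).

check_cohort <- function(x, need_tissue = FALSE) {
  need <- c("individual_id", "chain", "cdr3_aa", "read_count",
            if (need_tissue) "tissue")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "))
  if (any(!nzchar(x$individual_id))) stop("empty individual_id")
  if (any(grepl("\\*", x$cdr3_aa))) stop("cdr3_aa contains stop symbols")
  x
}

#' Tumor/normal repertoire overlap
#'
#' Pools amino-acid clonotypes across matched tumor/normal pairs and reports,
#' per chain, how many distinct CDR3s are unique to tumor, unique to normal,
#' or shared, along with a per-CDR3 table of read counts in each tissue and
#' the number of individuals carrying it.
#'
#' @param cohort long-format cohort data.frame (see above) with a `tissue`
#'   column; every individual must have both a tumor and a normal entry set.
#' @return list with `summary` (per-chain counts) and `per_cdr3`
#'   (chain, cdr3_aa, reads_tumor, reads_normal, n_individuals).
#' @export
overlap_summary <- function(cohort) {
  cohort <- check_cohort(cohort, need_tissue = TRUE)
  if (!all(cohort$tissue %in% c("tumor", "normal")))
    stop("tissue must be 'tumor' or 'normal'")
  u <- unique(cohort[c("individual_id", "tissue")])
  by_ind <- table(factor(u$individual_id),
                  factor(u$tissue, levels = c("tumor", "normal")))
  if (!all(by_ind == 1L))
    stop("mismatched ids: every individual needs one tumor and one normal repertoire")
  out <- list()
  per <- list()
  for (ch in sort(unique(cohort$chain))) {
    x <- cohort[cohort$chain == ch, ]
    tum <- unique(x$cdr3_aa[x$tissue == "tumor"])
    nor <- unique(x$cdr3_aa[x$tissue == "normal"])
    shared <- intersect(tum, nor)
    out[[ch]] <- data.frame(
      chain = ch,
      tumor_only = length(setdiff(tum, nor)),
      normal_only = length(setdiff(nor, tum)),
      shared = length(shared),
      stringsAsFactors = FALSE)
    all_cdr3 <- sort(union(tum, nor))
    rt <- tapply(x$read_count[x$tissue == "tumor"],
                 x$cdr3_aa[x$tissue == "tumor"], sum)
    rn <- tapply(x$read_count[x$tissue == "normal"],
                 x$cdr3_aa[x$tissue == "normal"], sum)
    ni <- tapply(x$individual_id, x$cdr3_aa,
                 function(v) length(unique(v)))
    per[[ch]] <- data.frame(
      chain = ch, cdr3_aa = all_cdr3,
      reads_tumor = as.integer(ifelse(is.na(rt[all_cdr3]), 0, rt[all_cdr3])),
      reads_normal = as.integer(ifelse(is.na(rn[all_cdr3]), 0, rn[all_cdr3])),
      n_individuals = as.integer(ni[all_cdr3]),
      stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(out, list(make.row.names = FALSE))),
       per_cdr3 = do.call(rbind, c(per, list(make.row.names = FALSE))))
}

#' Cross-individual CDR3 sharing profile
#'
#' For each amino-acid CDR3 (per chain): the number of individuals carrying
#' it, the number of distinct nucleotide variants encoding it (convergent
#' recombination; NA when no `cdr3_nt` column is supplied), total reads, and
#' an optional specificity label from a known-CDR3 annotation list.
#'
#' @param cohort long-format cohort data.frame (>= 2 individuals).
#' @param known optional data.frame (`cdr3_aa`, `specificity`) of published
#'   CDR3s with defined antigen specificity.
#' @return data.frame with `chain`, `cdr3_aa`, `n_individuals`,
#'   `n_nt_variants`, `total_reads` and (if `known` given) `specificity`.
#' @export
sharing_profile <- function(cohort, known = NULL) {
  cohort <- check_cohort(cohort)
  if (length(unique(cohort$individual_id)) < 2L)
    stop("sharing profile requires at least 2 individuals")
  key <- paste(cohort$chain, cohort$cdr3_aa, sep = "\r")
  ni <- tapply(cohort$individual_id, key, function(v) length(unique(v)))
  reads <- tapply(cohort$read_count, key, sum)
  nvar <- if ("cdr3_nt" %in% names(cohort))
    tapply(cohort$cdr3_nt, key, function(v) length(unique(v)))
  else setNames(rep(NA_integer_, length(ni)), names(ni))
  parts <- strsplit(names(ni), "\r", fixed = TRUE)
  out <- data.frame(
    chain = vapply(parts, `[`, character(1), 1L),
    cdr3_aa = vapply(parts, `[`, character(1), 2L),
    n_individuals = as.integer(ni),
    n_nt_variants = as.integer(nvar),
    total_reads = as.integer(reads),
    stringsAsFactors = FALSE)
  if (!is.null(known)) {
    out$specificity <- known$specificity[match(out$cdr3_aa, known$cdr3_aa)]
  }
  out <- out[order(out$chain, -out$n_individuals, out$cdr3_aa), ]
  rownames(out) <- NULL
  out
}

distinct_pairs_by_individual <- function(alpha_sets, beta_sets) {
  pairs <- mapply(function(a, b) {
    if (!length(a) || !length(b)) return(character(0))
    as.vector(outer(a, b, paste, sep = "\r"))
  }, alpha_sets, beta_sets, SIMPLIFY = FALSE)
  pairs
}

count_recurrent_pairs <- function(pairs_by_ind) {
  all_pairs <- unlist(pairs_by_ind, use.names = FALSE)
  if (!length(all_pairs)) return(0L)
  tab <- table(all_pairs)
  sum(tab >= 2L)
}

#' Alpha-beta pair co-occurrence randomization test
#'
#' Observed statistic: the number of distinct (alpha, beta) amino-acid CDR3
#' pairs found in at least two individuals, where each individual contributes
#' all pairwise combinations of its distinct alpha and beta CDR3s.  The null
#' is built by permuting which individual owns which beta repertoire (alpha
#' fixed; `permute = "both"` additionally permutes alpha) and recomputing the
#' statistic; the p value is the plain proportion of iterations with a
#' statistic greater than or equal to the observed one (minimum representable
#' p is 1/n_iterations).
#'
#' @param cohort long-format cohort data.frame containing both chains.
#' @param n_iterations number of permutations (default 100).
#' @param seed optional integer seed.
#' @param permute "beta" (default) or "both".
#' @return an object of class `pair_sharing_result`: list with
#'   `n_observed_recurrent_pairs`, `null_counts`, `p_value`, `n_iterations`.
#' @export
pair_cooccurrence_test <- function(cohort, n_iterations = 100, seed = NULL,
                                   permute = c("beta", "both")) {
  permute <- match.arg(permute)
  cohort <- check_cohort(cohort)
  inds <- sort(unique(cohort$individual_id))
  alpha_sets <- lapply(inds, function(i)
    unique(cohort$cdr3_aa[cohort$individual_id == i & cohort$chain == "alpha"]))
  beta_sets <- lapply(inds, function(i)
    unique(cohort$cdr3_aa[cohort$individual_id == i & cohort$chain == "beta"]))
  eligible <- lengths(alpha_sets) > 0 & lengths(beta_sets) > 0
  if (sum(eligible) < 2L)
    stop("need at least 2 individuals with non-empty alpha and beta repertoires")
  alpha_sets <- alpha_sets[eligible]
  beta_sets <- beta_sets[eligible]
  observed <- count_recurrent_pairs(
    distinct_pairs_by_individual(alpha_sets, beta_sets))
  k <- length(alpha_sets)
  null_counts <- with_seed(seed, vapply(seq_len(n_iterations), function(it) {
    b <- beta_sets[sample.int(k)]
    a <- if (permute == "both") alpha_sets[sample.int(k)] else alpha_sets
    count_recurrent_pairs(distinct_pairs_by_individual(a, b))
  }, integer(1)))
  structure(list(n_observed_recurrent_pairs = observed,
                 null_counts = null_counts,
                 p_value = mean(null_counts >= observed),
                 n_iterations = n_iterations),
            class = "pair_sharing_result")
}

#' @export
print.pair_sharing_result <- function(x, ...) {
  cat("Alpha-beta pair co-occurrence randomization test\n")
  cat(sprintf("  observed recurrent pairs: %d\n",
              x$n_observed_recurrent_pairs))
  cat(sprintf("  p = %.4g (%d iterations; null mean %.2f)\n", x$p_value,
              x$n_iterations, mean(x$null_counts)))
  invisible(x)
}

# identity = matches / length of the shorter sequence, best of left- and
# right-anchored ungapped comparison (CD-HIT stand-in; see vignette)
aa_identity <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  n <- min(na, nb)
  if (n == 0) return(0)
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  left <- sum(va[seq_len(n)] == vb[seq_len(n)])
  right <- sum(va[na - n + seq_len(n)] == vb[nb - n + seq_len(n)])
  max(left, right) / n
}

shared_kmer <- function(a, b, k) {
  if (nchar(a) < k || nchar(b) < k) return(TRUE)  # too short to prefilter
  ka <- substring(a, seq_len(nchar(a) - k + 1L), k:nchar(a))
  kb <- substring(b, seq_len(nchar(b) - k + 1L), k:nchar(b))
  any(ka %in% kb)
}

#' Greedy CDR3 clustering at an identity threshold
#'
#' Greedy incremental clustering in the style of CD-HIT: sequences are sorted
#' by length (descending, ties lexicographic), each joins the first cluster
#' whose representative it matches at >= `identity` (matches over the shorter
#' length, best of left/right-anchored ungapped comparison, with a shared
#' `word_length`-mer prefilter), otherwise it founds a new cluster.
#' Sequences shorter than `min_length` are discarded.
#'
#' @param sequences data.frame with `individual_id` and `cdr3_aa`.
#' @param identity identity threshold (default 0.95).
#' @param word_length k-mer length of the prefilter (default 5).
#' @param min_length minimum retained sequence length (default 6; mirrors
#'   the throw-away of sequences of length <= 5).
#' @return data.frame with `cluster_id`, `representative`, `individual_id`,
#'   `cdr3_aa`.
#' @export
cluster_cdr3 <- function(sequences, identity = 0.95, word_length = 5,
                         min_length = 6) {
  stopifnot(all(c("individual_id", "cdr3_aa") %in% names(sequences)))
  seqs <- sequences[nchar(sequences$cdr3_aa) >= min_length, , drop = FALSE]
  if (!nrow(seqs))
    return(data.frame(cluster_id = integer(0), representative = character(0),
                      individual_id = character(0), cdr3_aa = character(0)))
  ord <- order(-nchar(seqs$cdr3_aa), seqs$cdr3_aa, seqs$individual_id)
  seqs <- seqs[ord, ]
  reps <- character(0)
  assign_to <- integer(nrow(seqs))
  # cache: identical sequences always join the same cluster
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(seqs))) {
    s <- seqs$cdr3_aa[i]
    hit <- seen[[s]]
    if (!is.null(hit)) { assign_to[i] <- hit; next }
    found <- 0L
    for (cidx in seq_along(reps)) {
      if (!shared_kmer(s, reps[cidx], word_length)) next
      if (aa_identity(s, reps[cidx]) >= identity) { found <- cidx; break }
    }
    if (!found) {
      reps <- c(reps, s)
      found <- length(reps)
    }
    assign_to[i] <- found
    seen[[s]] <- found
  }
  out <- data.frame(cluster_id = assign_to,
                    representative = reps[assign_to],
                    individual_id = seqs$individual_id,
                    cdr3_aa = seqs$cdr3_aa,
                    stringsAsFactors = FALSE)
  out <- out[order(out$cluster_id, out$cdr3_aa, out$individual_id), ]
  rownames(out) <- NULL
  out
}

#' Peptide-MHC sharing resampling test
#'
#' Counts CDR3 clusters containing sequences from at least two individuals
#' who also share at least one pMHC, and compares against a resampling null:
#' the fraction of `n_trials` random individual pairs sharing a pMHC,
#' multiplied by the number of clusters containing two or more individuals
#' (Bonferroni-style correction, capped at 1).
#'
#' @param clusters cluster membership data.frame from [cluster_cdr3()].
#' @param pmhc data.frame with `individual_id` and `pmhc_id` (an opaque
#'   HLA-allele + peptide identifier).
#' @param n_trials number of random pairs (default 1e6).
#' @param seed optional integer seed.
#' @return list with `n_qualifying_clusters`, `n_two_individual_clusters`,
#'   `raw_fraction`, `adjusted_p`, `n_trials`.
#' @export
pmhc_sharing_test <- function(clusters, pmhc, n_trials = 1e6, seed = NULL) {
  stopifnot(all(c("individual_id", "pmhc_id") %in% names(pmhc)))
  if (!nrow(pmhc)) stop("pMHC table is empty")
  pmhc_sets <- tapply(pmhc$pmhc_id, pmhc$individual_id,
                      function(v) unique(v), simplify = FALSE)
  inds <- names(pmhc_sets)
  share_pmhc <- function(i, j)
    length(intersect(pmhc_sets[[i]], pmhc_sets[[j]])) > 0
  members <- tapply(clusters$individual_id, clusters$cluster_id,
                    function(v) unique(v), simplify = FALSE)
  multi <- members[lengths(members) >= 2L]
  qualifying <- sum(vapply(multi, function(m) {
    m <- intersect(m, inds)
    if (length(m) < 2L) return(FALSE)
    cmb <- utils::combn(m, 2L)
    any(apply(cmb, 2L, function(p) share_pmhc(p[1], p[2])))
  }, logical(1)))
  n_multi <- length(multi)
  if (length(inds) < 2L) stop("need at least 2 individuals with pMHC data")
  raw_fraction <- with_seed(seed, {
    i1 <- sample.int(length(inds), n_trials, replace = TRUE)
    # a distinct second individual per trial
    shift <- sample.int(length(inds) - 1L, n_trials, replace = TRUE)
    i2 <- 1L + (i1 - 1L + shift) %% length(inds)
    # vectorized sharing lookup over the distinct (i1, i2) combinations
    key <- paste(pmin(i1, i2), pmax(i1, i2))
    uk <- unique(key)
    parts <- strsplit(uk, " ", fixed = TRUE)
    share <- vapply(parts, function(p)
      share_pmhc(inds[as.integer(p[1])], inds[as.integer(p[2])]), logical(1))
    mean(share[match(key, uk)])
  })
  list(n_qualifying_clusters = as.integer(qualifying),
       n_two_individual_clusters = as.integer(n_multi),
       raw_fraction = raw_fraction,
       adjusted_p = min(1, raw_fraction * n_multi),
       n_trials = n_trials)
}
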