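#' Unbiased (minV, minJ) parameter-space exploration
#'
#' Scores every pairwise combination of minimum V and minimum J alignment
#' lengths (default 8..26 x 8..26, 361 pairs) on a positive control (reads
#' with a known truth CDR3 per transcript) and a negative control (reads with
#' no true CDR3).  For each pair, `n_recovered` counts truth transcripts
#' whose truth CDR3 nt sequence appears among the called CDR3s, `n_bogus`
#' counts distinct CDR3s called on the negative control, and relative
#' sensitivity is `n_recovered` divided by its maximum over the grid.
#'
#' Internally the reads are scanned once at the loosest stringency and every
#' cell is tabulated from the same candidate matches, which is equivalent to
#' (and much faster than) running [extract_cdr3()] per cell: the best V and J
#' matches per read do not depend on the thresholds, which only gate the
#' call.
#'
#' @param positive positive-control read data.frame (e.g. from
#'   [centered_reads()]).
#' @param truth the `tcr_repertoire` the positive reads derive from (its
#'   `cdr3_nt` column is the truth).
#' @param negative negative-control read data.frame (e.g. pooled
#'   [decoy_reads()] modes).
#' @param ref a `germline_reference`.
#' @param v_range,j_range integer vectors of thresholds (defaults 8:26).
#' @param params_base an [extraction_params()] supplying the mismatch budget
#'   and strand setting.
#' @param chain restrict scoring to one chain ("alpha"/"beta"), or "both" to
#'   score all calls together; defaults to the truth table's chain when
#'   unique, else "both".
#' @return an object of class `cdr3_grid`: a data.frame with one row per
#'   (min_v, min_j) pair and columns `min_v`, `min_j`, `n_recovered`,
#'   `n_bogus`, `relative_sensitivity`.
#' @export
grid_search <- function(positive, truth, negative, ref,
                        v_range = 8:26, j_range = 8:26,
                        params_base = extraction_params(), chain = NULL) {
  if (!length(v_range) || !length(j_range)) stop("empty threshold range")
  v_range <- sort(unique(as.integer(v_range)))
  j_range <- sort(unique(as.integer(j_range)))
  positive <- as_read_frame(positive)
  negative <- as_read_frame(negative)
  if (is.null(chain)) {
    ch <- unique(truth$chain)
    chain <- if (length(ch) == 1L) ch else "both"
  }
  chain_filter <- if (identical(chain, "both")) -1L else match(chain, CHAINS) - 1L

  reads <- c(positive$sequence, negative$sequence)
  read_negative <- c(rep(FALSE, nrow(positive)), rep(TRUE, nrow(negative)))

  cand <- scan_candidates(reads, ref, min(v_range), min(j_range),
                          params_base$max_mismatches,
                          params_base$both_strands)
  truth_tab <- table(truth$cdr3_nt)
  levels_all <- sort(unique(c(cand$cdr3, names(truth_tab))))
  cdr3_id <- match(cand$cdr3, levels_all)
  weight <- as.numeric(truth_tab[levels_all])
  weight[is.na(weight)] <- 0

  ord <- order(cand$read)
  res <- grid_tabulate_cpp(
    cand$read[ord], match(cand$chain[ord], CHAINS) - 1L,
    cand$v_seg[ord], cand$j_seg[ord],
    cand$v_len[ord], cand$j_len[ord], cdr3_id[ord],
    read_negative, weight, v_range, j_range, chain_filter)

  grid <- expand.grid(min_j = j_range, min_v = v_range)[c("min_v", "min_j")]
  grid$n_recovered <- as.vector(t(res$n_recovered))
  grid$n_bogus <- as.vector(t(res$n_bogus))
  max_rec <- max(grid$n_recovered)
  grid$relative_sensitivity <-
    if (max_rec > 0) grid$n_recovered / max_rec else NA_real_
  structure(grid,
            class = c("cdr3_grid", "data.frame"),
            chain = chain %||% "both",
            read_length = max(nchar(positive$sequence)),
            n_positive = nrow(positive), n_negative = nrow(negative),
            n_truth = nrow(truth))
}

#' @export
print.cdr3_grid <- function(x, ...) {
  cat("CDR3 extraction parameter grid:", nrow(x), "cells, chain =",
      attr(x, "chain"), ", read length =", attr(x, "read_length"), "\n")
  cat("positive reads:", attr(x, "n_positive"),
      "; negative reads:", attr(x, "n_negative"), "\n")
  best <- x[which.max(x$n_recovered), ]
  cat(sprintf("max recovery %d at (%d, %d)\n", as.integer(best$n_recovered),
              best$min_v, best$min_j))
  invisible(x)
}

#' Write a grid result as TSV
#'
#' @param grid a `cdr3_grid`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_grid <- function(grid, path) {
  write.table(as.data.frame(grid), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Select optimal extraction parameters from a grid
#'
#' Among cells whose negative-control call count does not exceed
#' `acceptable_bogus_max` (0 reproduces the theoretical 0% false discovery
#' rate), selects the pair with the highest recovery; ties are broken by
#' minimizing min_v + min_j, then min_v, then min_j.
#'
#' @param grid a `cdr3_grid`.
#' @param acceptable_bogus_max maximum tolerated distinct CDR3 calls on the
#'   negative control (default 0).
#' @return an object of class `optimal_selection`: list with `min_v`,
#'   `min_j`, `n_recovered`, `n_bogus`, `relative_sensitivity`,
#'   `acceptable_bogus_max`.
#' @export
select_optimal <- function(grid, acceptable_bogus_max = 0) {
  ok <- grid[grid$n_bogus <= acceptable_bogus_max, , drop = FALSE]
  if (!nrow(ok))
    stop("no parameter pair meets the false-discovery bound; ",
         "consider relaxing acceptable_bogus_max")
  ord <- order(-ok$n_recovered, ok$min_v + ok$min_j, ok$min_v, ok$min_j)
  best <- ok[ord[1L], ]
  structure(list(min_v = best$min_v, min_j = best$min_j,
                 n_recovered = best$n_recovered, n_bogus = best$n_bogus,
                 relative_sensitivity = best$relative_sensitivity,
                 acceptable_bogus_max = acceptable_bogus_max,
                 chain = attr(grid, "chain"),
                 read_length = attr(grid, "read_length")),
            class = "optimal_selection")
}

#' @export
print.optimal_selection <- function(x, ...) {
  cat(sprintf(
    "Optimal (minV, minJ) = (%d, %d) at <= %s bogus calls:\n",
    x$min_v, x$min_j, format(x$acceptable_bogus_max)))
  cat(sprintf("  recovered %d truth CDR3s (relative sensitivity %.3f), %d bogus\n",
              as.integer(x$n_recovered), x$relative_sensitivity,
              as.integer(x$n_bogus)))
  invisible(x)
}
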