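#' Junction diversity model
#'
#' Probability model for the nucleotide editing at V(D)J recombination
#' junctions: per-end exonuclease trimming (V 3', D 5', D 3', J 5') and
#' non-templated (N) nucleotide addition per junction.  Empirical junction
#' frequencies from repertoire sequencing are not redistributable, so the
#' defaults are parametric stand-ins chosen to reproduce a realistic CDR3
#' length spread: trims follow a truncated geometric distribution
#' (p = 0.25, support 0..12 per end) and insertion counts a truncated
#' Poisson (lambda = 4, support 0..15 per junction), with insertion bases
#' uniform over A/C/G/T.  Every distribution is overridable, including from a
#' TSV file (see [read_junction_model()]).
#'
#' @param deletion_probs named numeric vector of trim-length probabilities
#'   (names = number of nucleotides removed), applied to each recombining
#'   end, or a list with elements `v3`, `d5`, `d3`, `j5` for per-end control.
#' @param insertion_probs named numeric vector of insertion-length
#'   probabilities per junction.
#' @param insertion_base_probs probabilities of A, C, G, T for non-templated
#'   bases.
#' @return an object of class `junction_model`.
#' @export
junction_model <- function(deletion_probs = default_deletion_probs(),
                           insertion_probs = default_insertion_probs(),
                           insertion_base_probs = c(A = 0.25, C = 0.25,
                                                    G = 0.25, T = 0.25)) {
  if (!is.list(deletion_probs))
    deletion_probs <- list(v3 = deletion_probs, d5 = deletion_probs,
                           d3 = deletion_probs, j5 = deletion_probs)
  stopifnot(setequal(names(deletion_probs), c("v3", "d5", "d3", "j5")))
  deletion_probs <- lapply(deletion_probs, check_dist)
  insertion_probs <- check_dist(insertion_probs)
  stopifnot(setequal(names(insertion_base_probs), c("A", "C", "G", "T")),
            all(insertion_base_probs >= 0),
            abs(sum(insertion_base_probs) - 1) < 1e-8)
  structure(list(deletions = deletion_probs,
                 insertions = insertion_probs,
                 insertion_base_probs =
                   insertion_base_probs[c("A", "C", "G", "T")]),
            class = "junction_model")
}

check_dist <- function(p) {
  v <- as.integer(names(p))
  if (anyNA(v) || any(v < 0)) stop("distribution support must be named with non-negative integers")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("distribution probabilities must be non-negative and sum to 1")
  p[order(v)]
}

#' @rdname junction_model
#' @export
default_deletion_probs <- function() {
  p <- dgeom(0:12, prob = 0.25)
  setNames(p / sum(p), 0:12)
}

#' @rdname junction_model
#' @export
default_insertion_probs <- function() {
  p <- dpois(0:15, lambda = 4)
  setNames(p / sum(p), 0:15)
}

#' Read / write a junction model as TSV
#'
#' Format: three columns `distribution_name`, `value`, `probability`.
#' Distribution names are `del_v3`, `del_d5`, `del_d3`, `del_j5`, `ins` and
#' `insertion_base` (whose values are A/C/G/T).
#'
#' @param path file path.
#' @return [read_junction_model()] returns a `junction_model`;
#'   [write_junction_model()] returns `path` invisibly.
#' @export
read_junction_model <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("distribution_name", "value", "probability") %in% names(tab)))
  pick <- function(nm) {
    rows <- tab[tab$distribution_name == nm, ]
    setNames(rows$probability, rows$value)
  }
  junction_model(
    deletion_probs = list(v3 = pick("del_v3"), d5 = pick("del_d5"),
                          d3 = pick("del_d3"), j5 = pick("del_j5")),
    insertion_probs = pick("ins"),
    insertion_base_probs = pick("insertion_base"))
}

#' @rdname read_junction_model
#' @param model a `junction_model`.
#' @export
write_junction_model <- function(model, path) {
  rows <- list()
  for (end in names(model$deletions))
    rows[[paste0("del_", end)]] <- data.frame(
      distribution_name = paste0("del_", end),
      value = names(model$deletions[[end]]),
      probability = unname(model$deletions[[end]]))
  rows$ins <- data.frame(distribution_name = "ins",
                         value = names(model$insertions),
                         probability = unname(model$insertions))
  rows$base <- data.frame(distribution_name = "insertion_base",
                          value = names(model$insertion_base_probs),
                          probability = unname(model$insertion_base_probs))
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

sample_dist <- function(p, n) {
  vals <- as.integer(names(p))
  if (length(vals) == 1L) return(rep(vals, n))
  sample(vals, n, replace = TRUE, prob = p)
}

sample_insertion_strings <- function(model, lengths) {
  bases <- c("A", "C", "G", "T")
  vapply(lengths, function(L) {
    if (L <= 0) return("")
    paste(sample(bases, L, replace = TRUE,
                 prob = model$insertion_base_probs), collapse = "")
  }, character(1))
}

# Vectorized junction sampling; one row per event.
sample_junction_batch <- function(model, chain, n) {
  stopifnot(chain %in% CHAINS, n >= 1)
  if (chain == "beta") {
    data.frame(
      del_v3 = sample_dist(model$deletions$v3, n),
      del_d5 = sample_dist(model$deletions$d5, n),
      del_d3 = sample_dist(model$deletions$d3, n),
      del_j5 = sample_dist(model$deletions$j5, n),
      ins_vd = sample_insertion_strings(model, sample_dist(model$insertions, n)),
      ins_dj = sample_insertion_strings(model, sample_dist(model$insertions, n)),
      ins_vj = NA_character_,
      stringsAsFactors = FALSE)
  } else {
    # the single V-J insertion length is the rounded (half-up) mean of one
    # V-D draw and one D-J draw from the beta junction model
    vd <- sample_dist(model$insertions, n)
    dj <- sample_dist(model$insertions, n)
    len <- floor((vd + dj) / 2 + 0.5)
    data.frame(
      del_v3 = sample_dist(model$deletions$v3, n),
      del_d5 = NA_integer_, del_d3 = NA_integer_,
      del_j5 = sample_dist(model$deletions$j5, n),
      ins_vd = NA_character_, ins_dj = NA_character_,
      ins_vj = sample_insertion_strings(model, len),
      stringsAsFactors = FALSE)
  }
}

#' Sample a junction event
#'
#' Beta events carry independent V-D and D-J insertions and four trim counts;
#' alpha events carry a single V-J insertion whose length is the rounded mean
#' of one V-D draw and one D-J draw, plus V 3' and J 5' trims.
#'
#' @param model a `junction_model`.
#' @param chain "alpha" or "beta".
#' @param seed optional integer seed.
#' @return a one-row data.frame with the trim counts and insertion strings.
#' @export
sample_junction <- function(model, chain, seed = NULL) {
  with_seed(seed, sample_junction_batch(model, chain, 1L))
}
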