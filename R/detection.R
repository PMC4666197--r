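#' Published CDR3 detection-probability coefficients
#'
#' Coefficients of the logistic model of per-transcript CDR3 detection from
#' bulk RNA-seq:
#' \deqn{logit P(detected) = -5.38 + 1.98 \log_{10}(TPM)
#'   + 0.51 (depth / 10^7) + 0.04 L - 0.04 \ell}
#' where TPM is the transcript abundance in transcripts per million, depth
#' the total read count, L the read length in nt and \eqn{\ell} the CDR3
#' length in nt.  Available as the default coefficient set everywhere a
#' `coeffs` argument appears; refit on your own benchmark with
#' [fit_detection_model()].
#'
#' @format named numeric vector with elements `intercept`, `log10_tpm`,
#'   `depth_per_1e7`, `read_length`, `cdr3_length`.
#' @export
published_detection_coefficients <- c(
  intercept = -5.38, log10_tpm = 1.98, depth_per_1e7 = 0.51,
  read_length = 0.04, cdr3_length = -0.04)

check_coeffs <- function(coeffs) {
  need <- names(published_detection_coefficients)
  if (!all(need %in% names(coeffs)))
    stop("coefficients must be named: ", paste(need, collapse = ", "))
  coeffs <- coeffs[need]
  if (!all(is.finite(coeffs))) stop("coefficients must be finite")
  coeffs
}

detection_linear_predictor <- function(coeffs, tpm, depth, read_length,
                                       cdr3_length) {
  coeffs[["intercept"]] +
    coeffs[["log10_tpm"]] * log10(tpm) +
    coeffs[["depth_per_1e7"]] * depth / 1e7 +
    coeffs[["read_length"]] * read_length +
    coeffs[["cdr3_length"]] * cdr3_length
}

#' Predict CDR3 detection probability
#'
#' Inverse-logit of the detection model's linear predictor (see
#' [published_detection_coefficients]).
#'
#' @param coeffs named coefficient vector.
#' @param tpm transcript abundance in transcripts per million (> 0).
#' @param depth sequencing depth in total reads.
#' @param read_length read length in nt.
#' @param cdr3_length CDR3 length in nt.
#' @return detection probability (vectorized over the inputs).
#' @export
predict_detection <- function(coeffs = published_detection_coefficients,
                              tpm, depth, read_length, cdr3_length) {
  coeffs <- check_coeffs(coeffs)
  if (any(tpm <= 0)) stop("tpm must be positive (log10 undefined at 0)")
  plogis(detection_linear_predictor(coeffs, tpm, depth, read_length,
                                    cdr3_length))
}

#' Minimum sequencing depth for a target detection probability
#'
#' Closed-form solve of the detection model for depth at
#' `logit(target_p)`, plus the value rounded up to a reporting granularity
#' (default 1e7 reads, i.e. "tens of millions").
#'
#' @inheritParams predict_detection
#' @param target_p target detection probability (default 0.5).
#' @param granularity rounding-up unit in reads (default 1e7).
#' @return list with `exact` (reads) and `rounded` (reads, rounded up to
#'   `granularity`).
#' @export
min_depth_for_detection <- function(coeffs = published_detection_coefficients,
                                    tpm, read_length, cdr3_length,
                                    target_p = 0.5, granularity = 1e7) {
  coeffs <- check_coeffs(coeffs)
  if (coeffs[["depth_per_1e7"]] <= 0)
    stop("depth coefficient must be positive to solve for required depth")
  if (any(tpm <= 0)) stop("tpm must be positive")
  base <- coeffs[["intercept"]] +
    coeffs[["log10_tpm"]] * log10(tpm) +
    coeffs[["read_length"]] * read_length +
    coeffs[["cdr3_length"]] * cdr3_length
  exact <- (qlogis(target_p) - base) / coeffs[["depth_per_1e7"]] * 1e7
  list(exact = exact, rounded = ceiling(exact / granularity) * granularity)
}

#' TCR transcript fraction from percent T cell infiltration
#'
#' Healthy whole blood shows a TCR transcript fraction of about 1.5e-4;
#' lymphocytes are 20-40% of white blood cells (default 0.3, the midpoint),
#' so a pure lymphocyte population carries a fraction of about 5e-4 (one TCR
#' transcript in ~2000).  Assuming tumor-infiltrating lymphocytes (TIL)
#' resemble peripheral lymphocytes, a tumor with `til_percent`% TIL has
#' fraction `til_percent/100` times the pure-lymphocyte value.
#'
#' @param til_percent percent T cell infiltration (0-100).
#' @param blood_tcr_fraction whole-blood TCR transcript fraction.
#' @param lymphocyte_fraction lymphocyte share of white blood cells (0-1].
#' @return list with `fraction` (transcript fraction) and `tpm`
#'   (`fraction * 1e6`).
#' @export
til_to_tcr_fraction <- function(til_percent, blood_tcr_fraction = 1.5e-4,
                                lymphocyte_fraction = 0.3) {
  if (any(til_percent < 0 | til_percent > 100))
    stop("til_percent must be between 0 and 100")
  if (lymphocyte_fraction <= 0 || lymphocyte_fraction > 1)
    stop("lymphocyte_fraction must be in (0, 1]")
  pure <- blood_tcr_fraction / lymphocyte_fraction
  fraction <- pure * til_percent / 100
  list(fraction = fraction, tpm = fraction * 1e6)
}

#' Assemble per-transcript detection records from a benchmark run
#'
#' One record per truth transcript: its abundance (TPM), the dataset's depth
#' and read length, the truth CDR3 length, and whether the truth CDR3 nt
#' sequence appears in the extracted clonotype table.  Records violating
#' either detectability prerequisite - the transcript must be expressed
#' (TPM > 0) and the read length must exceed the CDR3 length - are flagged
#' `eligible = FALSE` and excluded from modelling.
#'
#' @param truth a `tcr_repertoire` data.frame with truth `cdr3_nt`.
#' @param abundance abundance table (`transcript_id`, `tpm`) from
#'   [simulate_rnaseq()].
#' @param extracted a `clonotype_table` (typically filtered).
#' @param depth,read_length the dataset's depth and read length.
#' @return data.frame of detection records with an `eligible` flag.
#' @export
build_detection_records <- function(truth, abundance, extracted, depth,
                                    read_length) {
  tpm <- abundance$tpm[match(truth$id, abundance$transcript_id)]
  cdr3_length <- nchar(truth$cdr3_nt)
  data.frame(
    transcript_id = truth$id,
    tpm = tpm,
    depth = depth,
    read_length = read_length,
    cdr3_length = cdr3_length,
    detected = truth$cdr3_nt %in% extracted$cdr3_nt,
    eligible = !is.na(tpm) & tpm > 0 & read_length > cdr3_length,
    stringsAsFactors = FALSE)
}

#' Fit the detection-probability model
#'
#' Multivariate logistic regression of detection on log10(TPM), depth/1e7,
#' read length and CDR3 length, fit on a random (seeded) half of the
#' eligible records, with sensitivity and specificity on the held-out half
#' reported at probability cutoff `cutoff`.
#'
#' @param records detection records (see [build_detection_records()]); rows
#'   with `eligible = FALSE` are dropped.
#' @param split_seed seed for the random half split.
#' @param cutoff classification cutoff for validation metrics (default 0.5).
#' @return an object of class `cdr3_detection_fit` with `coefficients` (same
#'   names as [published_detection_coefficients]), the underlying `glm` and
#'   `validation` metrics.  Methods: `print`, `summary`, `coef`, `predict`.
#' @export
fit_detection_model <- function(records, split_seed = 1, cutoff = 0.5) {
  if ("eligible" %in% names(records))
    records <- records[records$eligible, , drop = FALSE]
  if (!nrow(records)) stop("no eligible detection records")
  if (all(records$detected) || !any(records$detected))
    stop("complete separation: records are all ",
         if (all(records$detected)) "detected" else "undetected",
         "; the model is not identifiable")
  n <- nrow(records)
  train_idx <- with_seed(split_seed, sample.int(n, n %/% 2L))
  train <- records[train_idx, ]
  valid <- records[-train_idx, ]
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(detected ~ log10(tpm) + I(depth / 1e7) + read_length + cdr3_length,
        family = binomial(), data = train),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (anyNA(coef(fit)))
    stop("rank-deficient fit: covariate(s) without variation: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  if (!fit$converged || separation)
    stop("logistic fit did not converge (quasi-complete separation?); ",
         "check covariate spread in the benchmark records")
  co <- setNames(as.numeric(coef(fit)),
                 names(published_detection_coefficients))
  p_valid <- predict(fit, newdata = valid, type = "response")
  pred_pos <- p_valid >= cutoff
  validation <- list(
    sensitivity = mean(pred_pos[valid$detected]),
    specificity = mean(!pred_pos[!valid$detected]),
    cutoff = cutoff, n_train = nrow(train), n_validation = nrow(valid))
  structure(list(coefficients = co, glm = fit, validation = validation,
                 split_seed = split_seed),
            class = "cdr3_detection_fit")
}

#' @export
print.cdr3_detection_fit <- function(x, ...) {
  cat("CDR3 detection model (logistic):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("validation (cutoff %.2f): sensitivity %.1f%%, specificity %.1f%% (n = %d)\n",
              x$validation$cutoff, 100 * x$validation$sensitivity,
              100 * x$validation$specificity, x$validation$n_validation))
  invisible(x)
}

#' @export
summary.cdr3_detection_fit <- function(object, ...) {
  s <- summary(object$glm)
  or <- exp(object$coefficients[-1])
  cat("Odds ratios:\n")
  print(round(or, 4))
  s
}

#' @export
coef.cdr3_detection_fit <- function(object, ...) object$coefficients

#' @export
#' @rdname fit_detection_model
#' @param object a `cdr3_detection_fit`.
#' @param tpm,depth,read_length,cdr3_length covariates to predict at.
#' @param ... unused.
predict.cdr3_detection_fit <- function(object, tpm, depth, read_length,
                                       cdr3_length, ...) {
  predict_detection(object$coefficients, tpm, depth, read_length, cdr3_length)
}

#' Depth-requirement table over TIL percentages and CDR3 lengths
#'
#' Convenience wrapper combining [til_to_tcr_fraction()] and
#' [min_depth_for_detection()]: for each TIL percentage and CDR3 length, the
#' depth (in reads) required for a target detection probability.
#'
#' @inheritParams min_depth_for_detection
#' @param til_percents vector of TIL percentages.
#' @param cdr3_lengths vector of CDR3 lengths in nt.
#' @param read_length read length in nt.
#' @return data.frame with one row per combination.
#' @export
depth_requirement_table <- function(til_percents, cdr3_lengths,
                                    read_length = 50, target_p = 0.5,
                                    coeffs = published_detection_coefficients,
                                    granularity = 1e7) {
  grid <- expand.grid(til_percent = til_percents,
                      cdr3_length = cdr3_lengths)
  conv <- til_to_tcr_fraction(grid$til_percent)
  depths <- min_depth_for_detection(coeffs, tpm = conv$tpm,
                                    read_length = read_length,
                                    cdr3_length = grid$cdr3_length,
                                    target_p = target_p,
                                    granularity = granularity)
  data.frame(grid, tpm = conv$tpm, required_depth = depths$exact,
             required_depth_rounded = depths$rounded)
}
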