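test_that("the published model puts the 2% TIL tumor scenario just past even odds", {
  # TPM 10, 70M reads of 50 nt, 45-nt CDR3: linear predictor
  # -5.38 + 1.98 + 0.51*7 + 0.04*50 - 0.04*45 = 0.37
  p <- predict_detection(tpm = 10, depth = 7e7, read_length = 50,
                         cdr3_length = 45)
  expect_equal(p, plogis(0.37), tolerance = 1e-12)
  expect_gt(p, 0.5)
  # all-zero coefficients give coin-flip probability everywhere
  zero <- setNames(rep(0, 5), names(published_detection_coefficients))
  expect_equal(predict_detection(zero, 5, 1e6, 50, 45), 0.5)
  expect_error(predict_detection(tpm = 0, depth = 1, read_length = 50,
                                 cdr3_length = 45), "positive")
})

test_that("the abundance odds ratio matches the published value", {
  or <- exp(published_detection_coefficients[["log10_tpm"]])
  expect_lt(abs(or - 7.242), 0.01)
})

test_that("required depth solves the model exactly and rounds up to tens of millions", {
  d <- min_depth_for_detection(tpm = 10, read_length = 50, cdr3_length = 45)
  expect_equal(d$exact, 3.2 / 0.51 * 1e7, tolerance = 1e-9)
  expect_equal(d$rounded, 7e7)
  # inverse property on the logit scale
  p_back <- predict_detection(tpm = 10, depth = d$exact, read_length = 50,
                              cdr3_length = 45)
  expect_equal(qlogis(p_back), qlogis(0.5), tolerance = 1e-9)
  # more abundant transcripts need less depth
  d_hi <- min_depth_for_detection(tpm = 100, read_length = 50,
                                  cdr3_length = 45)
  expect_lt(d_hi$exact, d$exact)
  flipped <- published_detection_coefficients
  flipped[["depth_per_1e7"]] <- -0.1
  expect_error(min_depth_for_detection(flipped, 10, 50, 45), "positive")
})

test_that("detection probability is monotone in abundance, depth and CDR3 length", {
  tpms <- c(0.1, 1, 10, 100)
  expect_true(all(diff(predict_detection(tpm = tpms, depth = 1e7,
                                         read_length = 50,
                                         cdr3_length = 45)) > 0))
  depths <- c(1e6, 1e7, 1e8)
  expect_true(all(diff(predict_detection(tpm = 1, depth = depths,
                                         read_length = 50,
                                         cdr3_length = 45)) > 0))
  lens <- c(30, 45, 60)
  expect_true(all(diff(predict_detection(tpm = 1, depth = 1e7,
                                         read_length = 50,
                                         cdr3_length = lens)) < 0))
})

test_that("TIL percentages convert to the published transcript fractions", {
  expect_equal(til_to_tcr_fraction(100)$fraction, 5e-4)
  expect_equal(til_to_tcr_fraction(2)$fraction, 1e-5)
  expect_equal(1 / til_to_tcr_fraction(100)$fraction, 2000)
  expect_equal(til_to_tcr_fraction(2)$tpm, 10)
  expect_error(til_to_tcr_fraction(120), "between")
  expect_error(til_to_tcr_fraction(10, lymphocyte_fraction = 0), "lymphocyte")
})

test_that("detection records apply both detectability prerequisites", {
  truth <- data.frame(id = c("t1", "t2", "t3"),
                      cdr3_nt = c(strrep("TGC", 15), strrep("TGC", 18),
                                  strrep("TGC", 13)),
                      stringsAsFactors = FALSE)
  abundance <- data.frame(transcript_id = c("t1", "t2", "t3"),
                          tpm = c(5, 2, 0))
  extracted <- data.frame(cdr3_nt = strrep("TGC", 15))
  rec <- build_detection_records(truth, abundance, extracted,
                                 depth = 1e6, read_length = 50)
  expect_identical(rec$detected, c(TRUE, FALSE, FALSE))
  expect_identical(rec$eligible, c(TRUE, FALSE, FALSE))
  # t2: 54-nt CDR3 at 50-nt reads fails criterion (2); t3: unexpressed
})

test_that("the fit recovers known coefficients from self-simulated records", {
  simulate_records <- function(n, seed) {
    cdr3tools:::with_seed(seed, {
      tpm <- 10^runif(n, -1, 2.5)
      depth <- 10^runif(n, 4, 8)
      read_length <- sample(c(50, 76, 101), n, replace = TRUE)
      cdr3_length <- sample(30:60, n, replace = TRUE)
      lp <- predict_detection(published_detection_coefficients, tpm, depth,
                              read_length, cdr3_length)
      data.frame(tpm, depth, read_length, cdr3_length,
                 detected = runif(n) < lp, eligible = TRUE)
    })
  }
  for (seed in 1:5) {
    rec <- simulate_records(50000, 600 + seed)
    fit <- fit_detection_model(rec, split_seed = seed)
    rel_err <- abs(coef(fit) - published_detection_coefficients) /
      abs(published_detection_coefficients)
    expect_true(all(rel_err < 0.10))
    expect_gt(fit$validation$sensitivity, 0)
    expect_gt(fit$validation$specificity, 0)
  }
  # determinism: same records and split seed reproduce the coefficients
  rec <- simulate_records(20000, 700)
  f1 <- fit_detection_model(rec, split_seed = 3)
  f2 <- fit_detection_model(rec, split_seed = 3)
  expect_identical(coef(f1), coef(f2))
  # degenerate inputs are refused
  rec$detected <- TRUE
  expect_error(fit_detection_model(rec), "separation")
})

test_that("the fitted object predicts through its S3 method", {
  rec <- cdr3tools:::with_seed(800, {
    n <- 5000
    tpm <- 10^runif(n, -1, 2.5)
    depth <- 10^runif(n, 5, 8)
    read_length <- sample(c(50, 101), n, replace = TRUE)
    cdr3_length <- sample(36:57, n, replace = TRUE)
    lp <- predict_detection(published_detection_coefficients, tpm, depth,
                            read_length, cdr3_length)
    data.frame(tpm, depth, read_length, cdr3_length,
               detected = runif(n) < lp)
  })
  fit <- fit_detection_model(rec, split_seed = 1)
  p <- predict(fit, tpm = 10, depth = 7e7, read_length = 50, cdr3_length = 45)
  expect_true(p > 0 && p < 1)
  expect_equal(unname(coef(fit)["intercept"]),
               fit$coefficients[["intercept"]])
})

test_that("the depth-requirement table mirrors the conversion chain", {
  tab <- depth_requirement_table(til_percents = c(2, 10),
                                 cdr3_lengths = c(45, 54))
  expect_equal(nrow(tab), 4L)
  row <- tab[tab$til_percent == 2 & tab$cdr3_length == 45, ]
  expect_equal(row$tpm, 10)
  expect_equal(row$required_depth_rounded, 7e7)
})
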