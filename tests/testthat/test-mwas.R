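log2_features <- function(intensity, modes = NULL) {
  p <- nrow(intensity)
  meta <- data.frame(
    feature_id = rownames(intensity),
    mode = if (is.null(modes)) rep_len(c("C18-", "C18+"), p) else modes,
    mz = seq(100, 700, length.out = p),
    rt = seq(20, 500, length.out = p))
  new_feature_table(meta, intensity, qc = NULL, is_log2 = TRUE)
}

test_that("the mixture scan matches per-feature qgcomp fits", {
  set.seed(51)
  n <- 57
  X <- random_exposures(n)
  d <- quantize_exposures(X)
  covs <- make_cov(n)
  intensity <- matrix(rnorm(20 * n, 15), 20, n,
                      dimnames = list(sprintf("F%02d", 1:20),
                                      rownames(X)))
  ft <- log2_features(intensity)
  scan <- mwas_mixture_on_metabolome(d, ft, covs)
  for (i in c(1, 7, 20)) {
    fit <- fit_qgcomp(d, intensity[i, ], covs)
    expect_equal(scan$estimate[i], fit$psi, tolerance = 1e-10)
    expect_equal(scan$se[i], fit$se, tolerance = 1e-10)
    expect_equal(scan$p_value[i], fit$p_value, tolerance = 1e-10)
  }
})

test_that("a planted exposure-to-feature effect is recovered", {
  # average estimate across planted features at n = 500 sits within
  # 0.1 of the planted psi
  cfg <- sim_config(n_subjects = 500L, modes = tiny_modes,
                    n_signal_features = 10L, missing_rate = 0,
                    frac_low_detect = 0, frac_high_cv = 0, seed = 52L)
  st <- simulate_study(cfg)
  ft <- log2_transform(impute_half_min(st$features))
  scan <- mwas_mixture_on_metabolome(quantize_exposures(st$exposures),
                                     ft, st$covariates)
  planted <- scan$estimate[scan$feature_id %in%
                             st$truth$signal_feature_ids]
  expect_lt(abs(mean(planted) - cfg$psi_exposure_to_feature), 0.1)
})

test_that("null features give uniform p-values", {
  set.seed(53)
  n <- 100
  X <- random_exposures(n)
  d <- quantize_exposures(X)
  intensity <- matrix(rnorm(1000 * n, 15), 1000, n,
                      dimnames = list(sprintf("F%04d", 1:1000),
                                      rownames(X)))
  scan <- mwas_mixture_on_metabolome(d, log2_features(intensity))
  ks <- suppressWarnings(ks.test(scan$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("duplicate and constant features are handled predictably", {
  set.seed(54)
  n <- 40
  X <- random_exposures(n)
  d <- quantize_exposures(X)
  intensity <- matrix(rnorm(3 * n, 15), 3, n,
                      dimnames = list(c("F1", "F2", "F3"),
                                      rownames(X)))
  intensity[2, ] <- intensity[1, ]       # duplicate column
  intensity[3, ] <- 12                   # constant feature
  scan <- mwas_mixture_on_metabolome(d, log2_features(intensity))
  expect_equal(scan$estimate[1], scan$estimate[2])
  expect_equal(scan$p_value[1], scan$p_value[2])
  expect_true(scan$excluded[3])
  expect_true(is.na(scan$estimate[3]))
  # excluded features never count as significant
  flagged <- flag_significance(scan, 0.99, 0.99)
  expect_false(flagged$significant_raw[3])
})

test_that("the outcome scan estimates percent change per doubling", {
  set.seed(55)
  n <- 200
  intensity <- matrix(rnorm(30 * n, 15), 30, n,
                      dimnames = list(sprintf("F%02d", 1:30),
                                      sprintf("S%03d", 1:n)))
  beta <- -3.49
  y <- 100 + beta * intensity[5, ] + rnorm(n, sd = 3)
  names(y) <- colnames(intensity)
  scan <- mwas_metabolome_on_outcome(log2_features(intensity), y)
  expect_lt(abs(scan$estimate[5] - beta), 0.7)
  # squaring intensities doubles the log2 predictor: beta halves
  ft2 <- log2_features(2 * intensity)
  scan2 <- mwas_metabolome_on_outcome(ft2, y)
  expect_equal(scan2$estimate[5], scan$estimate[5] / 2,
               tolerance = 1e-10)
})

test_that("a permuted outcome rejects at the raw tier ~1% of the time", {
  set.seed(56)
  n <- 80
  intensity <- matrix(rnorm(2000 * n, 15), 2000, n,
                      dimnames = list(sprintf("F%04d", 1:2000),
                                      sprintf("S%03d", 1:n)))
  y <- rnorm(n, 0, 10)[sample(n)]
  names(y) <- colnames(intensity)
  scan <- mwas_metabolome_on_outcome(log2_features(intensity), y)
  rate <- mean(scan$p_value < 0.01)
  expect_lt(abs(rate - 0.01), 0.01)
})

test_that("scan records are order-independent", {
  set.seed(57)
  n <- 30
  X <- random_exposures(n)
  d <- quantize_exposures(X)
  intensity <- matrix(rnorm(12 * n, 15), 12, n,
                      dimnames = list(sprintf("F%02d", 1:12),
                                      rownames(X)))
  ft <- log2_features(intensity)
  perm <- sample(12)
  ft2 <- new_feature_table(ft$meta[perm, ],
                           ft$intensity[perm, ], NULL, TRUE)
  s1 <- mwas_mixture_on_metabolome(d, ft)
  s2 <- mwas_mixture_on_metabolome(d, ft2)
  expect_equal(s2$estimate, s1$estimate[perm])
  expect_equal(s2$p_value, s1$p_value[perm])
})

test_that("Kaiser-Guttman Meff counts eigenvalues above one", {
  set.seed(58)
  z <- rnorm(50)
  # two perfectly correlated variables: eigenvalues {2, 0} -> Meff 1
  expect_equal(as.integer(compute_meff(cbind(a = z, b = 2 * z + 3))),
               1L)
  # six variables in two tight blocks -> Meff 2
  f1 <- rnorm(200); f2 <- rnorm(200)
  M <- cbind(f1, f1 + rnorm(200, sd = 0.1), f1 + rnorm(200, sd = 0.1),
             f2, f2 + rnorm(200, sd = 0.1), f2 + rnorm(200, sd = 0.1))
  colnames(M) <- paste0("v", 1:6)
  expect_equal(as.integer(compute_meff(M)), 2L)
  # a single variable block is one test by definition
  expect_equal(as.integer(compute_meff(cbind(a = z))), 1L)
  # zero variance is an error naming the variable
  expect_error(compute_meff(cbind(a = z, flat = rep(1, 50))), "flat")
})

test_that("Meff respects the rank limit and the per-mode convention", {
  set.seed(59)
  n <- 20; p <- 120
  intensity <- matrix(rnorm(p * n, 15), p, n,
                      dimnames = list(sprintf("F%03d", 1:p),
                                      sprintf("S%03d", 1:n)))
  modes <- rep(c("C18-", "C18+", "HILIC-", "HILIC+"), each = p / 4)
  ft <- log2_features(intensity, modes)
  per_mode <- compute_meff(ft, by_mode = TRUE)
  joint <- compute_meff(ft, by_mode = FALSE)
  expect_lte(as.integer(joint), min(p, n - 1))
  blocks <- attr(per_mode, "per_block")
  expect_true(all(blocks <= pmin(p / 4, n - 1)))
  expect_equal(as.integer(per_mode), sum(blocks))
})

test_that("the adjusted alpha divides by the summed Meff", {
  expect_equal(adjusted_alpha(1, 1), 0.025)
  expect_equal(adjusted_alpha(2, 62), 0.05 / 64)
  # monotone decreasing in each argument
  expect_lt(adjusted_alpha(3, 62), adjusted_alpha(2, 62))
  expect_lt(adjusted_alpha(2, 63), adjusted_alpha(2, 62))
  expect_error(adjusted_alpha(0, 5), "meff")
})

test_that("significance summaries format counts with percentages", {
  expect_equal(format_count_pct(74, 3619), "74 (2.04%)")
  expect_equal(format_count_pct(0, 5292), "0 (0%)")
  expect_equal(format_count_pct(10, 10), "10 (100%)")
  set.seed(60)
  n <- 30
  d <- quantize_exposures(random_exposures(n))
  intensity <- matrix(rnorm(40 * n, 15), 40, n,
                      dimnames = list(sprintf("F%02d", 1:40),
                                      sprintf("S%03d", 1:n)))
  scan <- mwas_mixture_on_metabolome(d, log2_features(intensity))
  summ <- significance_summary(scan, raw_alpha = 0.5,
                               alpha_adjusted = 1e-8)
  expect_setequal(summ$mode, c("C18-", "C18+"))
  expect_equal(sum(summ$n_features), 40)
  expect_true(all(summ$n_raw >= summ$n_adjusted))
})
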