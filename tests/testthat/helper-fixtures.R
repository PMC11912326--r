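# Small study configurations and deterministic covariate tables used
# across the suite. Feature counts are scaled down so the default test
# run stays fast; the generator itself is unchanged.

tiny_modes <- c("C18-" = 60L, "C18+" = 60L, "HILIC-" = 60L,
                "HILIC+" = 60L)

tiny_config <- function(...) {
  sim_config(modes = tiny_modes, n_signal_features = 8L, ...)
}

# Balanced, collinearity-free covariate table (no RNG involved).
make_cov <- function(n) {
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    sex = rep_len(c("male", "female"), n),
    race = rep_len(c("Non-Hispanic white", "Others",
                     "Non-Hispanic white"), n),
    age_months = 180 + seq_len(n) %% 37,
    income = rep_len(c("<$25,000", "$25,000-$74,999", ">=$75,000",
                       "unknown", "<$25,000"), n),
    bmi = 45 + (seq_len(n) * 7) %% 20,
    site = rep_len(c("A", "B"), n),
    stringsAsFactors = FALSE)
}

# Correlated log-normal exposure matrix without the full config
# machinery, for estimator-level tests.
random_exposures <- function(n, k = 6, rho = 0.4) {
  R <- matrix(rho, k, k); diag(R) <- 1
  Z <- matrix(rnorm(n * k), n, k) %*% chol(R)
  X <- exp(Z)
  colnames(X) <- paste0("chem", seq_len(k))
  rownames(X) <- sprintf("S%03d", seq_len(n))
  X
}
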