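# Independent oracles, deliberately written against base R model-fitting
# machinery rather than the package's own linear-algebra path.

# G-computation contrast: fit the linear model with stats::lm, then take
# the mean predicted outcome with every quantile index incremented by
# one minus the mean prediction at the observed indices.
qg_contrast_oracle <- function(design, outcome, covariates = NULL) {
  idx <- as.data.frame(design$indices)
  chems <- names(idx)
  d <- cbind(y = outcome, idx)
  if (!is.null(covariates)) {
    C <- as.data.frame(covariate_model_matrix(covariates))
    names(C) <- paste0("c", seq_along(C))
    d <- cbind(d, C)
  }
  fit <- stats::lm(y ~ ., data = d)
  d1 <- d
  d1[chems] <- d1[chems] + 1
  mean(stats::predict(fit, d1)) - mean(stats::predict(fit, d))
}

# Exhaustive hypergeometric upper-tail sum for the ORA p-value.
hyper_tail_oracle <- function(k, K, N, n) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Spearman correlation of two vectors from the rank formula directly.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
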