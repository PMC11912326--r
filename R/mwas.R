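# Align a feature table's subject columns with a design/covariate order.
align_subjects <- function(features, subj) {
  have <- colnames(features$intensity)
  if (!setequal(have, subj)) {
    stop("feature table and design cover different subjects")
  }
  features$intensity <- features$intensity[, subj, drop = FALSE]
  features
}

#' MWAS scan: POP mixture on every metabolic feature
#'
#' Fits one quantile-g-computation model per feature with the log2
#' feature intensity as the outcome and the shared covariate set,
#' recording the overall mixture effect psi (log2 units per simultaneous
#' one-quartile increase), its standard error and two-sided Wald
#' p-value. Constant features are flagged `excluded` and carry NA
#' estimates.
#'
#' @param design A `quantized_design` over the exposure panel.
#' @param features A preprocessed (imputed, log2) `feature_table`.
#' @param covariates Covariate data.frame or NULL.
#' @param include_site Adjust for study site?
#' @return A data.frame of class `mwas_result` with columns
#'   `feature_id`, `mode`, `mz`, `rt`, `estimate`, `se`, `p_value`,
#'   `excluded`; attribute `direction = "exposure_to_feature"`.
#' @export
mwas_mixture_on_metabolome <- function(design, features,
                                       covariates = NULL,
                                       include_site = FALSE) {
  stopifnot(inherits(design, "quantized_design"),
            inherits(features, "feature_table"))
  if (!features$is_log2) stop("features must be log2-transformed")
  if (anyNA(features$intensity)) stop("features must be imputed first")
  idx <- design$indices
  features <- align_subjects(features, rownames(idx))
  C <- covariate_model_matrix(covariates, include_site)
  X <- cbind("(Intercept)" = 1, idx, C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient MWAS design")
  df <- nrow(X) - ncol(X)
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot),
                                drop = FALSE]
  chems <- colnames(idx)
  c_psi <- sum(XtXinv[seq_along(chems) + 1L, seq_along(chems) + 1L])

  Y <- t(features$intensity)                   # subjects x features
  coef <- qr.coef(qrX, Y)
  rss <- colSums((Y - X %*% coef)^2)
  sigma2 <- rss / df
  psi <- colSums(coef[chems, , drop = FALSE])
  se <- sqrt(sigma2 * c_psi)
  const <- apply(Y, 2, function(v) stats::sd(v) == 0)
  psi[const] <- NA_real_; se[const] <- NA_real_
  p <- 2 * stats::pnorm(-abs(psi / se))
  out <- data.frame(
    feature_id = features$meta$feature_id,
    mode = features$meta$mode,
    mz = features$meta$mz, rt = features$meta$rt,
    estimate = unname(psi), se = unname(se), p_value = unname(p),
    excluded = unname(const),
    stringsAsFactors = FALSE)
  structure(out, direction = "exposure_to_feature",
            class = c("mwas_result", "data.frame"))
}

#' MWAS scan: every metabolic feature on a blood-pressure outcome
#'
#' Fits one linear model per feature with the percent-change outcome as
#' response and the log2 feature intensity as predictor (plus the shared
#' covariates), so beta reads as the percent change in the outcome per
#' doubling of the feature's intensity.
#'
#' @param features A preprocessed (imputed, log2) `feature_table`.
#' @param outcome Numeric percent-change vector, named by subject id or
#'   ordered like the feature columns.
#' @param covariates Covariate data.frame or NULL.
#' @param include_site Adjust for study site?
#' @return A data.frame of class `mwas_result`, attribute
#'   `direction = "feature_to_outcome"`.
#' @export
mwas_metabolome_on_outcome <- function(features, outcome,
                                       covariates = NULL,
                                       include_site = FALSE) {
  stopifnot(inherits(features, "feature_table"))
  if (!features$is_log2) stop("features must be log2-transformed")
  if (anyNA(features$intensity)) stop("features must be imputed first")
  subj <- colnames(features$intensity)
  if (!is.null(names(outcome))) {
    if (!setequal(names(outcome), subj)) {
      stop("outcome and feature table cover different subjects")
    }
    outcome <- outcome[subj]
  }
  stopifnot(length(outcome) == length(subj))
  C <- covariate_model_matrix(covariates, include_site)
  X0 <- cbind("(Intercept)" = rep(1, length(outcome)), C)
  p <- n_features(features)
  est <- se <- rep(NA_real_, p)
  const <- apply(features$intensity, 1, function(v) stats::sd(v) == 0)
  for (i in which(!const)) {
    X <- cbind(X0, feature = features$intensity[i, ])
    fit <- ols_fit(X, outcome)
    est[i] <- fit$coef[["feature"]]
    se[i] <- sqrt(fit$vcov["feature", "feature"])
  }
  out <- data.frame(
    feature_id = features$meta$feature_id,
    mode = features$meta$mode,
    mz = features$meta$mz, rt = features$meta$rt,
    estimate = est, se = se,
    p_value = 2 * stats::pnorm(-abs(est / se)),
    excluded = unname(const),
    stringsAsFactors = FALSE)
  structure(out, direction = "feature_to_outcome",
            class = c("mwas_result", "data.frame"))
}

# Kaiser-Guttman count from correlation-matrix eigenvalues: strictly
# greater than one. An exactly-unit eigenvalue (degenerate, e.g. an
# identity correlation target) counts zero, with a warning.
meff_from_eigenvalues <- function(ev, tol = 1e-8) {
  if (any(abs(ev - 1) <= tol)) {
    warning("eigenvalue(s) exactly 1 do not count towards Meff ",
            "(Kaiser-Guttman rule is strict)")
  }
  sum(ev - 1 > tol)
}

#' Effective number of tests (Kaiser-Guttman rule)
#'
#' Counts the eigenvalues of the variables' correlation matrix that
#' strictly exceed one. For feature tables the default computes Meff
#' within each analytical mode and sums across modes: a joint
#' decomposition of p >> n features is rank-limited at n - 1, so
#' per-mode summation is the operative convention (a joint option is
#' kept for sensitivity). Eigenvalues are obtained from the SVD of the
#' standardized data matrix, equivalent to the correlation-matrix
#' eigendecomposition.
#'
#' @param x A numeric matrix (observations x variables) or a log2
#'   `feature_table`.
#' @param ... Passed to methods.
#' @return Integer Meff with attribute `eigenvalues` (per block).
#' @export
compute_meff <- function(x, ...) UseMethod("compute_meff")

cor_eigenvalues <- function(M, what = "variable") {
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance ", what, "(s): ",
         paste(utils::head(colnames(M)[sds == 0], 3), collapse = ", "))
  }
  Z <- scale(M)
  d <- svd(Z, nu = 0, nv = 0)$d
  d^2 / (nrow(M) - 1)
}

#' @rdname compute_meff
#' @export
compute_meff.default <- function(x, ...) {
  stopifnot(is.matrix(x), ncol(x) >= 1)
  if (ncol(x) == 1) {
    return(structure(1L, eigenvalues = list(1)))
  }
  ev <- cor_eigenvalues(x)
  structure(meff_from_eigenvalues(ev), eigenvalues = list(ev))
}

#' @rdname compute_meff
#' @param by_mode Compute per analytical mode and sum (default TRUE)?
#' @export
compute_meff.feature_table <- function(x, by_mode = TRUE, ...) {
  if (!x$is_log2) stop("compute Meff on log2-transformed features")
  if (anyNA(x$intensity)) stop("impute before computing Meff")
  blocks <- if (by_mode) split(x$meta$feature_id, x$meta$mode)
            else list(all = x$meta$feature_id)
  evs <- lapply(blocks, function(ids) {
    M <- t(x$intensity[ids, , drop = FALSE])
    cor_eigenvalues(M, what = "feature")
  })
  counts <- vapply(evs, meff_from_eigenvalues, integer(1))
  structure(as.integer(sum(counts)), eigenvalues = evs,
            per_block = counts)
}

#' PCA-adjusted significance threshold
#'
#' Family-wise alpha divided by the summed effective numbers of tests of
#' the predictor and response blocks: with Meff 2 for the exposure block
#' and 62 for the metabolome, 0.05/64 = 0.00078; with a single selected
#' outcome (Meff 1), 0.05/63 = 0.0008 (2 and 1 significant figures as
#' conventionally displayed).
#'
#' @param meff_exposure Meff of the predictor block (>= 1).
#' @param meff_outcome Meff of the response block (>= 1).
#' @param alpha_family Family-wise alpha (default 0.05).
#' @return The adjusted alpha at full precision.
#' @export
adjusted_alpha <- function(meff_exposure, meff_outcome,
                           alpha_family = 0.05) {
  stopifnot(meff_exposure >= 1, meff_outcome >= 1)
  alpha_family / (meff_exposure + meff_outcome)
}

#' Attach significance flags to an MWAS result
#'
#' @param results An `mwas_result`.
#' @param raw_alpha Raw p-value tier (default 0.01).
#' @param alpha_adjusted PCA-adjusted tier, or NULL to leave unset.
#' @return The result with logical `significant_raw` and
#'   `significant_adjusted` columns (excluded features are FALSE).
#' @export
flag_significance <- function(results, raw_alpha = 0.01,
                              alpha_adjusted = NULL) {
  stopifnot(inherits(results, "mwas_result"))
  p <- results$p_value
  results$significant_raw <- !is.na(p) & p < raw_alpha
  results$significant_adjusted <-
    if (is.null(alpha_adjusted)) NA else !is.na(p) & p < alpha_adjusted
  attr(results, "raw_alpha") <- raw_alpha
  attr(results, "alpha_adjusted") <- alpha_adjusted
  results
}

#' Format a significant-feature count with its percentage
#'
#' Percentage of the mode's total, rounded to two decimals with trailing
#' zeros trimmed; a zero count renders "0 (0%)".
#'
#' @param n Count of significant features.
#' @param total Total features in the mode.
#' @return Character, e.g. `"74 (2.04%)"`.
#' @export
format_count_pct <- function(n, total) {
  if (n == 0) return("0 (0%)")
  sprintf("%d (%s%%)", n, as.character(round(100 * n / total, 2)))
}

#' Per-mode significance summary of an MWAS scan
#'
#' Counts (with percentages of the mode's feature total) at the raw
#' p < `raw_alpha` tier and at the PCA-adjusted tier.
#'
#' @param results An `mwas_result` (flags are recomputed from p-values).
#' @param raw_alpha Raw tier (default 0.01).
#' @param alpha_adjusted Adjusted tier, or NULL to omit that column.
#' @return data.frame with one row per mode: `mode`, `n_features`,
#'   `n_raw`, `raw`, and if requested `n_adjusted`, `adjusted`.
#' @export
significance_summary <- function(results, raw_alpha = 0.01,
                                 alpha_adjusted = NULL) {
  stopifnot(inherits(results, "mwas_result"))
  res <- flag_significance(results, raw_alpha, alpha_adjusted)
  counted <- res[!res$excluded, , drop = FALSE]
  modes <- unique(results$mode)
  rows <- lapply(modes, function(m) {
    sub <- counted[counted$mode == m, , drop = FALSE]
    total <- sum(results$mode == m & !results$excluded)
    n_raw <- sum(sub$significant_raw)
    row <- data.frame(mode = m, n_features = total, n_raw = n_raw,
                      raw = format_count_pct(n_raw, total),
                      stringsAsFactors = FALSE)
    if (!is.null(alpha_adjusted)) {
      n_adj <- sum(sub$significant_adjusted)
      row$n_adjusted <- n_adj
      row$adjusted <- format_count_pct(n_adj, total)
    }
    row
  })
  do.call(rbind, rows)
}
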