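# Quantile indices for a matrix of exposures. Cutpoints are empirical
# quantiles with linear interpolation (type 7); a value exactly equal to
# a cutpoint falls in the lower category. Because the type-7 interpolation
# weight depends only on n and the probability, the resulting indices are
# invariant to any strictly increasing transform of the values.
quantile_indices <- function(X, q = 4L) {
  idx <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (length(unique(x)) < 2) {
      stop("chemical '", colnames(X)[j],
           "' has fewer than 2 distinct values; cannot quantize")
    }
    cut <- stats::quantile(x, probs = seq_len(q - 1) / q, type = 7,
                           names = FALSE)
    rowSums(outer(x, cut, `>`))
  }, numeric(nrow(X)))
  dimnames(idx) <- dimnames(X)
  storage.mode(idx) <- "integer"
  idx
}

#' Quantize exposures into quantile indices
#'
#' Assigns each chemical's concentrations to quantile categories
#' 0..q-1 using empirical cutpoints (linear interpolation); ties at a
#' cutpoint fall to the lower category. The assignment is rank-based and
#' therefore invariant to strictly monotone re-expression of any
#' chemical (e.g. log transforms). Heavy ties - typical when non-detects
#' share the LOD/sqrt(2) value - trigger a warning reporting the
#' realized category sizes.
#'
#' @param panel An `exposure_panel`, or a numeric subjects x chemicals
#'   matrix.
#' @param q Number of quantile categories (default 4, i.e. quartiles).
#' @return A `quantized_design`: list with `indices` (integer matrix),
#'   `q`, `cutpoints` (per chemical) and `values` (the original
#'   concentrations, kept so submixtures can re-quantize).
#' @export
quantize_exposures <- function(panel, q = 4L) {
  X <- if (inherits(panel, "exposure_panel")) panel$concentrations
       else panel
  stopifnot(is.matrix(X), q >= 2)
  idx <- quantile_indices(X, q)
  cutpoints <- lapply(seq_len(ncol(X)), function(j)
    stats::quantile(X[, j], probs = seq_len(q - 1) / q, type = 7,
                    names = FALSE))
  names(cutpoints) <- colnames(X)
  sizes <- apply(idx + 1L, 2, tabulate, nbins = q)
  if (any(sizes == 0)) {
    bad <- colnames(X)[colSums(sizes == 0) > 0]
    warning("heavy ties leave empty quantile categories for: ",
            paste(bad, collapse = ", "), "; realized sizes: ",
            paste(apply(sizes[, colnames(X) %in% bad, drop = FALSE], 2,
                        paste, collapse = "/"), collapse = "; "))
  }
  structure(list(indices = idx, q = as.integer(q),
                 cutpoints = cutpoints, values = X),
            class = "quantized_design")
}

#' @export
print.quantized_design <- function(x, ...) {
  cat("Quantized design:", nrow(x$indices), "subjects x",
      ncol(x$indices), "chemicals, q =", x$q, "\n")
  invisible(x)
}

#' Covariate design matrix with the standard adjustment coding
#'
#' Race/ethnicity and sex enter as single indicators, parents' income as
#' three indicators against the "<$25,000" reference, age in months and
#' baseline BMI as continuous terms; study site is an optional extra
#' indicator for sensitivity analyses.
#'
#' @param covariates data.frame with `sex`, `race`, `age_months`,
#'   `income`, `bmi` (and `site` if `include_site`), or NULL.
#' @param include_site Add the study-site indicator?
#' @return A numeric matrix without intercept, or NULL.
#' @export
covariate_model_matrix <- function(covariates, include_site = FALSE) {
  if (is.null(covariates)) return(NULL)
  need <- c("sex", "race", "age_months", "income", "bmi")
  if (!all(need %in% names(covariates))) {
    stop("covariate table must contain: ", paste(need, collapse = ", "))
  }
  d <- data.frame(
    sex = factor(covariates$sex, levels = c("male", "female")),
    race = factor(covariates$race,
                  levels = c("Non-Hispanic white", "Others")),
    age_months = covariates$age_months,
    income = factor(covariates$income,
                    levels = c("<$25,000", "$25,000-$74,999",
                               ">=$75,000", "unknown")),
    bmi = covariates$bmi)
  if (anyNA(d)) stop("covariates contain missing or unrecognized values")
  form <- ~ sex + race + age_months + income + bmi
  if (include_site) {
    d$site <- factor(covariates$site)
    form <- ~ sex + race + age_months + income + bmi + site
  }
  # categories absent from the sample contribute no indicator
  d <- droplevels(d)
  mm <- stats::model.matrix(form, d)
  mm[, -1, drop = FALSE]
}

# Shared OLS core: returns coefficients, their covariance and residual
# variance, failing loudly on rank deficiency.
ols_fit <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  coef <- qr.coef(qrX, y)
  res <- y - X %*% coef
  df <- nrow(X) - ncol(X)
  if (df <= 0) stop("more parameters than observations")
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot),
                                drop = FALSE]
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  list(coef = coef, vcov = sigma2 * XtXinv, sigma2 = sigma2, df = df)
}

#' Fit a linear quantile g-computation model
#'
#' Ordinary least squares of the outcome on all chemical quantile
#' indices jointly, plus covariates. The overall mixture effect psi is
#' the sum of the chemical-index coefficients - the expected outcome
#' change for a simultaneous one-quantile increase in every chemical -
#' with Var(psi) = 1' Sigma 1 over the chemical-coefficient covariance
#' block and a normal-approximation 95% CI. The individual chemical
#' coefficients are the partial effects; their sum equals psi by
#' construction (asserted on every fit).
#'
#' @param design A `quantized_design` from [quantize_exposures()].
#' @param outcome Numeric outcome vector (percent-change outcomes enter
#'   in percentage points, log2 feature intensities in log2 units).
#' @param covariates Covariate data.frame (see
#'   [covariate_model_matrix()]) or NULL for an unadjusted fit.
#' @param include_site Adjust for study site (sensitivity analysis)?
#' @param level Confidence level (default 0.95).
#' @param outcome_label Optional label stored on the fit.
#' @return A `qgcomp_fit`: `psi`, `se`, `ci_low`, `ci_high`, `p_value`,
#'   `partial_effects`, `positive_partials`, `negative_partials`,
#'   `coefficients` (full), `n`, `q`, `outcome`.
#' @export
fit_qgcomp <- function(design, outcome, covariates = NULL,
                       include_site = FALSE, level = 0.95,
                       outcome_label = NULL) {
  stopifnot(inherits(design, "quantized_design"))
  idx <- design$indices
  n <- nrow(idx)
  stopifnot(length(outcome) == n)
  C <- covariate_model_matrix(covariates, include_site)
  X <- cbind("(Intercept)" = 1, idx, C)
  fit <- ols_fit(X, outcome)
  chems <- colnames(idx)
  partial <- fit$coef[chems]
  psi <- sum(partial)
  var_psi <- sum(fit$vcov[chems, chems])
  se <- sqrt(var_psi)
  z <- stats::qnorm(1 - (1 - level) / 2)
  stopifnot(abs(sum(partial) - psi) < 1e-10)
  structure(list(
    psi = psi, se = se,
    ci_low = psi - z * se, ci_high = psi + z * se,
    p_value = 2 * stats::pnorm(-abs(psi / se)),
    partial_effects = partial,
    positive_partials = partial[partial > 0],
    negative_partials = partial[partial < 0],
    coefficients = fit$coef,
    vcov = fit$vcov,
    n = n, q = design$q, level = level,
    outcome = outcome_label %||% "outcome"
  ), class = "qgcomp_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.qgcomp_fit <- function(x, digits = 3, ...) {
  cat("Quantile g-computation fit (", x$outcome, ", n = ", x$n,
      ", q = ", x$q, ")\n", sep = "")
  cat(sprintf("  psi = %.*f  [%.*f, %.*f]  p = %.3g\n",
              digits, x$psi, digits, x$ci_low, digits, x$ci_high,
              x$p_value))
  cat("  partial effects:\n")
  print(round(x$partial_effects, digits))
  invisible(x)
}

#' Fit a chemical-class submixture
#'
#' Re-quantizes only the named subset of chemicals and fits the same
#' model on that subset alone; the other chemicals are excluded from the
#' model entirely. Used for the OCP-only and PCB-only sensitivity
#' analyses.
#'
#' @inheritParams fit_qgcomp
#' @param subset Character vector of chemical names to keep.
#' @return A `qgcomp_fit` for the submixture.
#' @export
fit_submixture <- function(design, outcome, covariates = NULL,
                           subset, include_site = FALSE, level = 0.95,
                           outcome_label = NULL) {
  stopifnot(inherits(design, "quantized_design"), length(subset) > 0)
  unknown <- setdiff(subset, colnames(design$values))
  if (length(unknown) > 0) {
    stop("unknown chemical name(s): ", paste(unknown, collapse = ", "))
  }
  sub_design <- quantize_exposures(
    design$values[, subset, drop = FALSE], q = design$q)
  fit_qgcomp(sub_design, outcome, covariates, include_site, level,
             outcome_label)
}
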