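#' Substitute concentrations below the limit of detection
#'
#' Left-censored cells are replaced by LOD/sqrt(2), the standard
#' substitution for non-detects in exposure panels; uncensored cells are
#' untouched.
#'
#' @param panel An `exposure_panel`.
#' @return The panel with censored cells set to `lod/sqrt(2)`.
#' @export
substitute_below_lod <- function(panel) {
  stopifnot(inherits(panel, "exposure_panel"))
  cens_by_chem <- colSums(panel$censored) > 0
  if (any(cens_by_chem & (is.na(panel$lod) | panel$lod <= 0))) {
    bad <- names(which(cens_by_chem & (is.na(panel$lod) |
                                         panel$lod <= 0)))
    stop("censored cells but no valid LOD for: ",
         paste(bad, collapse = ", "))
  }
  sub <- matrix(panel$lod / sqrt(2), nrow(panel$concentrations),
                ncol(panel$concentrations), byrow = TRUE)
  panel$concentrations[panel$censored] <- sub[panel$censored]
  panel
}

#' Log2-transform concentrations or intensities
#'
#' Right-skewed concentrations and intensities are analysed on the log2
#' scale, so model coefficients read as effects per doubling.
#'
#' @param x An `exposure_panel` or `feature_table`.
#' @param ... Unused.
#' @return The object with log2 values: for an exposure panel the `log2`
#'   matrix is filled; for a feature table the intensity matrix is
#'   replaced and `is_log2` set.
#' @export
log2_transform <- function(x, ...) UseMethod("log2_transform")

#' @rdname log2_transform
#' @export
log2_transform.exposure_panel <- function(x, ...) {
  check_positive(x$concentrations, "concentration")
  x$log2 <- log2(x$concentrations)
  x
}

#' @rdname log2_transform
#' @export
log2_transform.feature_table <- function(x, ...) {
  if (x$is_log2) return(x)
  if (anyNA(x$intensity)) {
    stop("feature intensities contain missing values; impute first ",
         "(see impute_half_min)")
  }
  check_positive(x$intensity, "intensity")
  x$intensity <- log2(x$intensity)
  x$is_log2 <- TRUE
  x
}

check_positive <- function(m, what) {
  bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-positive ", what, " at [",
         paste(rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
               sep = ", "), "] cannot be log-transformed")
  }
  invisible(TRUE)
}

#' Per-feature detection rate and QC coefficient of variation
#'
#' Detection rate is the fraction of non-missing subject cells (QC
#' replicates are excluded from the denominator); the QC CV is SD/mean
#' of the pooled-QC replicate intensities on the raw scale.
#'
#' @param table A raw-scale `feature_table` with QC columns.
#' @return The table with `detection_rate` and `qc_cv` columns added to
#'   its metadata.
#' @export
feature_qc_stats <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$qc) || ncol(table$qc) < 2) {
    stop("QC replicate columns are required to compute QC CV")
  }
  table$meta$detection_rate <-
    rowMeans(!is.na(table$intensity))
  qc_mean <- rowMeans(table$qc)
  qc_sd <- apply(table$qc, 1, stats::sd)
  table$meta$qc_cv <- qc_sd / qc_mean
  table
}

#' Filter features on detection rate and QC coefficient of variation
#'
#' Retains exactly the features with detection rate >= `min_detection`
#' and QC CV <= `max_qc_cv`, preserving order. The counts removed by each
#' rule are recorded in the `filter_log` attribute. Idempotent.
#'
#' @param table A raw-scale `feature_table` with QC columns.
#' @param min_detection Minimum fraction of subjects with an observed
#'   intensity (default 0.20).
#' @param max_qc_cv Maximum QC CV (default 0.30).
#' @return The filtered `feature_table`.
#' @export
filter_features <- function(table, min_detection = 0.20,
                            max_qc_cv = 0.30) {
  table <- feature_qc_stats(table)
  low_det <- table$meta$detection_rate < min_detection
  high_cv <- table$meta$qc_cv > max_qc_cv
  keep <- !low_det & !high_cv
  out <- subset_features(table, table$meta$feature_id[keep])
  attr(out, "filter_log") <- data.frame(
    rule = c("detection_rate", "qc_cv"),
    threshold = c(min_detection, max_qc_cv),
    removed = c(sum(low_det), sum(high_cv & !low_det)))
  out
}

#' Impute missing intensities with half the feature minimum
#'
#' Missing cells of each feature are set to half of that feature's
#' minimum observed intensity, computed on the raw scale before any log
#' transform.
#'
#' @param table A raw-scale `feature_table`.
#' @return The table with no missing subject intensities.
#' @export
impute_half_min <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$is_log2) {
    stop("half-minimum imputation operates on the raw intensity scale")
  }
  obs <- rowSums(!is.na(table$intensity))
  if (any(obs == 0)) {
    stop("feature(s) entirely missing (should have been filtered): ",
         paste(utils::head(table$meta$feature_id[obs == 0], 3),
               collapse = ", "))
  }
  mins <- apply(table$intensity, 1, min, na.rm = TRUE)
  na_idx <- which(is.na(table$intensity), arr.ind = TRUE)
  if (nrow(na_idx) > 0) {
    table$intensity[na_idx] <- mins[na_idx[, 1]] / 2
  }
  table
}

#' Percent change from baseline
#'
#' @param value_followup Follow-up value(s).
#' @param value_baseline Baseline value(s), non-zero.
#' @return `100 * (followup - baseline) / baseline`.
#' @export
percent_change <- function(value_followup, value_baseline) {
  if (any(value_baseline == 0)) {
    stop("percent change undefined for zero baseline")
  }
  100 * (value_followup - value_baseline) / value_baseline
}

#' Mean arterial pressure and pulse pressure
#'
#' MAP = (SBP + 2 DBP)/3 summarises average pressure over a cardiac
#' cycle; pulse pressure = SBP - DBP indexes arterial stiffness. Both
#' closed forms are exact.
#'
#' @param sbp Systolic blood pressure (mmHg).
#' @param dbp Diastolic blood pressure (mmHg).
#' @return List with `map` and `pulse_pressure` (mmHg). A DBP exceeding
#'   SBP is flagged with a warning but still computed.
#' @export
derive_pressure_indices <- function(sbp, dbp) {
  if (any(dbp > sbp)) {
    warning("DBP exceeds SBP for ", sum(dbp > sbp),
            " observation(s); indices computed anyway")
  }
  list(map = (sbp + 2 * dbp) / 3, pulse_pressure = sbp - dbp)
}

#' Percent-change outcomes for all measures and follow-up visits
#'
#' Derives MAP and pulse pressure at each visit and returns percent
#' changes from baseline for SBP, DBP, MAP and pulse pressure at six
#' months and five years.
#'
#' @param bp A `bp_panel` (see [generate_blood_pressure()]).
#' @return data.frame with `subject_id` and columns
#'   `<measure>_pct_<visit>` for measure in sbp, dbp, map, pulse and
#'   visit in month6, year5.
#' @export
bp_outcomes <- function(bp) {
  measures <- function(visit) {
    sbp <- bp[[paste0("sbp_", visit)]]
    dbp <- bp[[paste0("dbp_", visit)]]
    idx <- derive_pressure_indices(sbp, dbp)
    list(sbp = sbp, dbp = dbp, map = idx$map, pulse = idx$pulse_pressure)
  }
  base <- measures("baseline")
  out <- data.frame(subject_id = bp$subject_id,
                    stringsAsFactors = FALSE)
  for (visit in c("month6", "year5")) {
    fu <- measures(visit)
    for (m in names(base)) {
      out[[paste0(m, "_pct_", visit)]] <- percent_change(fu[[m]],
                                                         base[[m]])
    }
  }
  out
}

#' Geometric mean with confidence interval
#'
#' `exp(mean(log x))` with a normal-theory interval on the log scale:
#' `exp(mean(log x) +/- z * sd(log x) / sqrt(n))`.
#'
#' @param values Positive numeric vector, length >= 2.
#' @param level Confidence level (default 0.95).
#' @return Named vector `gm`, `lo`, `hi`.
#' @export
geometric_mean_ci <- function(values, level = 0.95) {
  if (any(values <= 0)) stop("geometric mean requires positive values")
  if (length(values) < 2) stop("need at least two values")
  lx <- log(values)
  m <- mean(lx)
  se <- stats::sd(lx) / sqrt(length(lx))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(gm = exp(m), lo = exp(m - z * se), hi = exp(m + z * se))
}

#' Spearman rank-correlation matrix
#'
#' Rank-based with average ranks for ties. Constant columns yield NA
#' entries with a warning rather than a silent zero.
#'
#' @param x Numeric matrix (observations x variables) or an
#'   `exposure_panel` (uses concentrations).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(x) {
  if (inherits(x, "exposure_panel")) x <- x$concentrations
  stopifnot(is.matrix(x), nrow(x) >= 3)
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  out <- suppressWarnings(stats::cor(x, method = "spearman"))
  if (any(const)) {
    warning("constant column(s) with undefined rank correlation: ",
            paste(colnames(x)[const], collapse = ", "))
    out[const, ] <- NA_real_
    out[, const] <- NA_real_
  }
  diag(out) <- 1
  out
}

#' Descriptive statistics for an exposure panel
#'
#' Concentration-scale summary per chemical: detection rate, geometric
#' mean with 95% CI, and the five-number spread, computed after LOD
#' substitution but before any log transform.
#'
#' @param panel An `exposure_panel` (ideally after
#'   [substitute_below_lod()]).
#' @return data.frame, one row per chemical.
#' @export
describe_exposures <- function(panel) {
  X <- panel$concentrations
  gm <- t(apply(X, 2, geometric_mean_ci))
  qs <- t(apply(X, 2, stats::quantile,
                probs = c(0, 0.25, 0.5, 0.75, 1)))
  data.frame(
    chemical = colnames(X),
    detection_rate = 1 - colMeans(panel$censored),
    gm = gm[, "gm"], gm_lo = gm[, "lo"], gm_hi = gm[, "hi"],
    min = qs[, 1], p25 = qs[, 2], median = qs[, 3], p75 = qs[, 4],
    max = qs[, 5],
    row.names = NULL, stringsAsFactors = FALSE)
}
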